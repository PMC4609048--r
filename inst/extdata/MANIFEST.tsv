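file	md5
serious_adverse_effects.tsv	41ce3a5dc34f7a84a55b88cd68397e16
effectiveness_arms.tsv	649eaffd2049ebc92c83904f8b7d76ea
nonserious_arms.tsv	9e874ab49414a69ba0e66de9acc404b8
risk_limits.tsv	90a67a352cab16d0ec989b09eeae9688
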