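stratum,label,concordant,discordant,doubly_ascertained
overall,totals,24,109,13
by-sex,F,22,66,12
by-sex,M,2,43,1
by-HLA,H+,9,31,5
by-HLA,H-,11,42,6
by-HLA,totals,20,73,11
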