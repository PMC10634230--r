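>XIST1.1|oligo_xist11
GUUGUCAAUGGUCCUUCAA
>RNA9.2s|oligo_rna92s
AGCUUAACCUGUCCUUCAA
>RNA9.2a|oligo_rna92a
UUGAAGGACAGGUUAAGCU
>polyA|oligo_polya
AAAAAAAAAAAAAAAAAAA
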