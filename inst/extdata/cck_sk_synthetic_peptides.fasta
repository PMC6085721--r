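>sk1_pep1 synthetic CCK/SK-type peptide pair member (gene 1, peptide 1)
EGAWSYDYGHSLMRF
>sk2_pep1 synthetic CCK/SK-type peptide pair member (gene 2, peptide 1)
EGSWSYDYGHNLMRF
>sk1_pep2 synthetic CCK/SK-type peptide pair member (gene 1, peptide 2)
NYGDFLRF
>sk2_pep2 synthetic CCK/SK-type peptide pair member (gene 2, peptide 2)
NYGDFLRF
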