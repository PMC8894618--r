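# Animal hemoglobin-subunit symbols mapped onto the annotated human beta-family
# subunits. The published end note names the alias set but not the per-symbol
# mapping; the split below uses both human genes and is otherwise arbitrary.
alias	canonical
Hba1	HBB
Hbbl	HBB
Hbm	HBB
Hbad	HBD
Hbz1	HBD
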