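# Patient-level outcome counts from the same published transplant cohort:
# 15 patients progressed to BOS (4 preceded by confirmed BOS 0-p), 46 never
# developed BOS (43 of them never staged BOS 0-p), 7 patients were ever staged
# BOS 0-p (4 progressed to BOS, 3 ended follow-up unresolved).
quantity	count
n_bos	15
n_bos_preceded_by_bos0p	4
n_never_bos	46
n_never_bos_never_bos0p	43
n_ever_bos0p	7
n_bos0p_progressed	4
n_terminal_bos0p	3
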