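# Per-patient clinical summary for the 22-patient reference MEG cohort.
# plan_lobes: lobar regions treated by resection or, for P16 (synthetic
#   assignment from its SEEG target, radiofrequency thermocoagulation only),
#   the SEEG target region; semicolon-separated "<hemi> <lobe>" labels.
# engel: Engel class one year after surgery ("2/3" kept verbatim; empty for
#   the two non-operated patients P9 and P10).
id,n_ied,plan_lobes,engel,operated
P1,36,R F,3,TRUE
P2,30,L P,1,TRUE
P3,61,L T,1,TRUE
P4,92,L T,4,TRUE
P5,18,L T,1,TRUE
P6,41,R F,1,TRUE
P7,8,L T,2/3,TRUE
P8,14,R T;R P,1,TRUE
P9,100,,,FALSE
P10,45,,,FALSE
P11,75,L F,1,TRUE
P12,35,R F,1,TRUE
P13,47,L T;L O,1,TRUE
P14,17,L P,2,TRUE
P15,39,R C;R P,1,TRUE
P16,62,R T,1,TRUE
P17,52,R T,1,TRUE
P18,12,R T;R O,1,TRUE
P19,52,R F;R T,4,TRUE
P20,72,L T,2,TRUE
P21,64,R T;R P;R O,1,TRUE
P22,82,L T,3,TRUE
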