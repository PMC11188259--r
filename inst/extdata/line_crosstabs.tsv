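# Per-line serology x diplotype cross-tabulations for the five lines with I-system
# segregation (WL1, WL2, WL7, and the NIU DNA-bank pedigree and non-pedigree sets).
# Counts with reconstructed = no are transcribed from the published per-line results.
# Counts with reconstructed = yes are not printed in the main text (heterozygote
# outcomes of the NIU sets, identity of discordant diplotypes); they are reconstructed
# to be consistent with the printed per-line consistency rates (90% for both NIU sets)
# and with the reported error mode (het/hom serological confusion).
line_id	serology	hapA	hapB	n	reconstructed
WL1	I2I2	H02	H02	19	no
WL1	I8I8	H01	H01	14	no
WL1	I8I8	H01	H02	14	no
WL1	I2I8	H01	H02	40	no
WL1	I2I8	H01	H01	2	no
WL2	I2I2	H02	H02	29	no
WL2	I8I8	H03	H03	6	no
WL2	I8I8	H02	H03	1	yes
WL2	I2I8	H02	H03	38	no
WL2	I2I8	H03	H03	5	no
WL7	I2I2	H02	H02	4	no
WL7	I8I8	H01	H01	15	no
WL7	I2I8	H01	H02	32	no
WL7	I2I8	H01	H01	11	no
NIU_pedigree	I2I2	H02	H02	21	no
NIU_pedigree	I8I8	H04	H04	5	no
NIU_pedigree	I8I8	H03	H03	1	no
NIU_pedigree	I8I8	H02	H03	2	yes
NIU_pedigree	I8I8	H02	H04	1	yes
NIU_pedigree	I2I8	H02	H04	9	yes
NIU_pedigree	I2I8	H02	H02	1	yes
NIU_nonpedigree	I2I2	H02	H02	15	no
NIU_nonpedigree	I2I2	H02	H03	1	yes
NIU_nonpedigree	I8I8	H03	H03	38	no
NIU_nonpedigree	I8I8	H02	H03	2	yes
NIU_nonpedigree	I2I8	H02	H03	26	yes
NIU_nonpedigree	I2I8	H03	H03	6	yes
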