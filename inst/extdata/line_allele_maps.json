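{
  "WL1": {"I2": ["H02"], "I8": ["H01"]},
  "WL2": {"I2": ["H02"], "I8": ["H03"]},
  "WL7": {"I2": ["H02"], "I8": ["H01"]},
  "NIU_pedigree": {"I2": ["H02"], "I8": ["H03", "H04"]},
  "NIU_nonpedigree": {"I2": ["H02"], "I8": ["H03", "H04"]}
}
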