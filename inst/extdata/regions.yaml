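regions:
- label: r_31-36
  category: APR
  start: 31
  end: 36
- label: r_47-51
  category: APR
  start: 47
  end: 51
- label: r_114-118
  category: APR
  start: 114
  end: 118
- label: r_129-139
  category: APR
  start: 129
  end: 139
- label: r_261-265
  category: APR
  start: 261
  end: 265
- label: r_325-329
  category: APR
  start: 325
  end: 329
- label: r_387-402
  category: APR
  start: 387
  end: 402
- label: r_26-28
  category: hotspot
  start: 26
  end: 28
- label: r_126-128
  category: hotspot
  start: 126
  end: 128
- label: r_152-153
  category: hotspot
  start: 152
  end: 153
- label: r_288-290
  category: hotspot
  start: 288
  end: 290
- label: r_348-352
  category: hotspot
  start: 348
  end: 352
- label: r_405-411
  category: hotspot
  start: 405
  end: 411
- label: r_437-442
  category: hotspot
  start: 437
  end: 442
- label: r_187-190
  category: hotspot
  start: 187
  end: 190
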