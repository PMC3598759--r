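groups:
- start: C00
  end: C14
  group: head_neck
- start: C15
  end: C17
  group: upper_gi
- start: C18
  end: C21
  group: colorectal
- start: C22
  end: C29
  group: upper_gi
- start: C30
  end: C32
  group: head_neck
- start: C33
  end: C39
  group: respiratory
- start: C40
  end: C42
  group: bone_connective
- start: C43
  end: C43
  group: melanoma
- start: C45
  end: C49
  group: bone_connective
- start: C50
  end: C50
  group: breast
- start: C51
  end: C59
  group: gynaecological
- start: C60
  end: C68
  group: urogenital
- start: C69
  end: C72
  group: neurological
- start: C73
  end: C75
  group: thyroid_endocrine
- start: C76
  end: C76
  group: ill_defined_unknown
- start: C80
  end: C80
  group: ill_defined_unknown
- start: C81
  end: C96
  group: lymphohaematopoeitic
secondary:
- C77
- C79
out_of_scope:
- C44
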