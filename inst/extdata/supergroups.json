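{
  "_comment": "Example supergroup definitions for merging small areas before percentage comparison. The 'core and belt' auditory grouping is illustrative (synthetic membership list following the standard marmoset auditory nomenclature).",
  "core and belt": ["AuA1", "AuR", "AuRT", "AuCM", "AuCL", "AuAL", "AuRM", "AuRTM", "AuRTL"]
}
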