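# Fixture provenance

- `phenotypes_table1.tsv`: transcription of the published table of knockout
  phenotypes for the 26 ortholog pairs deleted in both *F. graminearum* and
  *N. crassa*, with free-text phenotype descriptions mapped onto the package's
  phenotype classes (the first canonical stage at which the strain deviates
  from wild type; beak/spore-release defects are Stage-5, ascus defects
  Stage-3, perithecium-number/protoperithecium defects Stage-1). The 23-gene
  F. graminearum ranked-list subset is this table minus FGSG_02751,
  FGSG_09475 and FGSG_13162, which were deleted outside the ranked-list
  screen; that subset carries 17 non-wild-type calls out of 23.
- `published_comparisons.tsv`: 2x2 contingency counts of the published
  knockout hit-rate comparisons (row-wise cells a,b,c,d).
- `stage_mapping_*.tsv`: default sample-point -> canonical-stage maps for the
  eight-point (*Neurospora*) and six-point (*Fusarium*) sampling designs;
  the original collapse is unpublished, so these are package defaults.
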