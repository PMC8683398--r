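# Curated grouping of collapsed enrichment sets into functional subsets.
# Keys are subset names; values list the collapsed-set names (the
# representative term ids reported by collapse_terms) each subset unions.
chaperone_response:
  - T001
  - T005
glutathione_related:
  - T002
  - T004
mitochondrial:
  - T003
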