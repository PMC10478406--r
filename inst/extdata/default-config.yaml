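# Declarative configuration for the AUC-extraction pipeline.
# Values here override the package defaults (see ?auc_config); indicator
# lists are data, not code.
exclusion:
  max_short_words: 10
  pk_mesh:
    - Pharmacokinetics
    - Biological Availability
    - Metabolic Clearance Rate
    - Tissue Distribution
    - Drug Elimination
  meta_pubtypes:
    - Meta-Analysis
  meta_title:
    - meta-analysis
    - meta analysis
    - pooled analysis
  tutorial_title:
    - tutorial
extraction:
  window: 250
thresholds: [0.7, 0.8, 0.9]
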