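dyad_promoter_search     Dyad and gapped searches on a synthetic promoter with a planted CTGT-N8-ACAG inverted repeat
protein_motif_discovery  Gibbs-sampling discovery of a planted protein motif in synthetic sequences
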