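# Dyad searches on a synthetic promoter region.
#
# A 125-bp synthetic promoter carries one planted CTGT-N8-ACAG inverted
# repeat, the canonical layout of an SOS-box-like operator. Three tools are
# pointed at it:
#   * dyad_motif_discovery: string-based repeat discovery (4+-1 bp dyad,
#     8+-1 bp spacer, 2 mismatches allowed),
#   * gapped_search: substring dyad query CTGW ... WCAG with a 6-10 bp spacer,
#   * dyad_pattern_search: PSFM half-site scan scored in Ri bits.

library(seqsuite)

promoter <- generate_random_genome(
  length = 125, gc_fraction = 0.5, seed = 20,
  dyad = list(start = 51, half = "CTGT", spacer = 8, inverted = TRUE),
  id = "synthetic_promoter")
cat("planted feature:\n")
print(promoter$truth)

cat("\nstring-based dyad discovery (4+-1 bp dyad, 8+-1 bp spacer, <=2 mismatches):\n")
hits <- dyad_motif_discovery(promoter$sequence, dyad_len = 4, d_tol = 1,
                             spacer = 8, s_tol = 1, max_mismatch = 2,
                             orientation = "INVERTED")
print(head(hits[order(hits$score), ], 5))

cat("\ngapped substring search, CTGW ... WCAG, spacer 6-10, <=2 mismatches:\n")
print(gapped_search(promoter$sequence, "CTGW", "WCAG", max_mismatch = 2,
                    spacer_min = 6, spacer_max = 10))

cat("\nPSFM dyad pattern search (half-site CTGT, Ri bits):\n")
ri <- dyad_pattern_search(promoter$sequence, "CTGT", spacer_min = 6,
                          spacer_max = 10, orientation = "INVERTED",
                          threshold_bits = 8)
print(ri[which.max(ri$score), ])
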