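# Gibbs-sampling motif discovery on synthetic protein sequences.
#
# Ten 80-residue synthetic proteins each carry one instance of a conserved
# 10-residue motif at a random position. The Gibbs site sampler (one site per
# sequence) is asked to find it, and the result is rendered as a text
# consensus logo with the per-position information content in bits.

library(seqsuite)

planted <- generate_planted(n_sequences = 10, length = 80,
                            motif = "VAAGEWLVDK", seed = 33)

res <- gibbs_sample(planted$sequences, w = 10, iterations = 20, seed = 7)
print(res)

cat("\nrecovered site positions vs planted truth:\n")
print(merge(res$sites, planted$truth, by = "sequence_id"))

cat("\nconsensus logo (height = positional information, bits):\n")
print(render_consensus_logo(res$psfm, rows = 8))
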