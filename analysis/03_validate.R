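#!/usr/bin/env Rscript
# Step 3 — parameter recovery against the stored ground truth.
#
# Compares the inferred fishing period, fishing-cluster classification
# and camera event partition with what the generator actually did.

library(fishwolf)

m <- run_validate("results/dataset")

cat(sprintf("period endpoint error (days): start %+d, end %+d\n",
            m$period_start_error_days, m$period_end_error_days))
cat(sprintf("fishing-cluster precision %.2f, recall %.2f (%d predicted / %d expected)\n",
            m$cluster_precision, m$cluster_recall,
            m$n_predicted_fishing_clusters, m$n_expected_fishing_clusters))
cat(sprintf("camera event partition agreement: %.3f\n",
            m$event_partition_agreement))
cat("metrics written to results/dataset/analysis/validation.json\n")
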