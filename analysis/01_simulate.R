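#!/usr/bin/env Rscript
# Simulate the study cohort: 1000 genes x 120 samples in equal normal /
# transition / AML thirds, a constant planted steady state, three planted
# unbalanced processes at 20x the log-scale noise SD, 1% stable
# transcripts, and a pseudotime marker gene loading on the state axis.
# Writes the expression matrix, sample metadata and ground-truth tables
# under results/cohort/.

library(passfec)

seed <- 42L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(seed = seed)
gen <- generate_dataset(spec)

write_expression_matrix(gen$expression, file.path(out, "matrix.tsv"))
write.table(gen$meta, file.path(out, "metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tr <- gen$truth
write.table(data.frame(sample_id = names(tr$stage), stage = tr$stage,
                       state_coordinate = tr$state_coordinate,
                       expected_code = tr$expected_codes),
            file.path(out, "truth_samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(tr$lambda), tr$lambda),
            file.path(out, "truth_lambda.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(tr$stable_gene_ids, file.path(out, "truth_stable_genes.txt"))
write_run_manifest(file.path(out, "manifest.json"), seed = seed,
                   n_genes = spec$n_genes, n_samples = spec$n_samples,
                   n_processes = spec$n_processes, noise_sd = spec$noise_sd,
                   marker_gene = tr$marker_gene_id)

cat(sprintf("Cohort: %d genes x %d samples (%s)\n", nrow(gen$expression),
            ncol(gen$expression), paste(table(tr$stage)[c("normal", "transition", "AML")],
                                        collapse = "/")))
cat(sprintf("Planted: %d processes at %.0fx noise SD; marker gene %s; %d stable transcripts\n",
            spec$n_processes, spec$process_amplitudes[1] / spec$noise_sd,
            tr$marker_gene_id, length(tr$stable_gene_ids)))
cat(sprintf("Distinct planted PaSSS codes: %d\n", length(unique(tr$expected_codes))))
cat("Tables written to", out, "\n")
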