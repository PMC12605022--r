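#!/usr/bin/env Rscript
# Microstate-conditioned source connectivity: sLORETA inversion of the
# state-specific GFP-peak maps (polarity-normalised, template span
# removed), sector parcellation, Pearson correlation, pooled per group
# and state, with thresholded edge lists for circos-style plotting.

source("analysis/00_config.R")
cfg <- analysis_config()
state <- readRDS("scratch/preprocessed.rds")
fits <- readRDS("scratch/fits.rds")
prepped <- state$prepped
cohort <- state$cohort

inv <- build_sloreta_inverse(cohort$leadfield, alpha = cfg$alpha)
message(sprintf("sLORETA inverse: %d sources, %d regions, alpha = %g",
                inv$n_sources, length(cohort$parcellation$region_names),
                inv$alpha))

pooled <- lapply(names(prepped), function(g) {
  grp <- prepped[[g]]
  ft <- fits[[g]]
  per_state <- lapply(seq_len(ft$model$k), function(s) {
    cms <- list()
    for (i in seq_along(grp)) {
      seg <- backfit(ft$model, grp[[i]]$clean, ft$gfps[[i]])
      sd_ <- extract_state_data(grp[[i]]$clean, seg, s, gfp = ft$gfps[[i]],
                                align_to = ft$model, remove_span = TRUE)
      if (sd_$n < 10) next
      reg <- parcellate(apply_inverse(inv, sd_$data), cohort$parcellation)
      cms[[length(cms) + 1L]] <- pearson_connectivity(reg, ft$state_names[s])
    }
    summarize_connectivity(cms)
  })
  names(per_state) <- ft$state_names
  per_state[order(names(per_state))]
})
names(pooled) <- names(prepped)
saveRDS(pooled, "scratch/pooled_connectivity.rds")

conn <- do.call(rbind, lapply(names(pooled), function(g)
  do.call(rbind, lapply(pooled[[g]], function(s)
    data.frame(group = g, state = s$state, mean = s$mean, sd = s$sd,
               n = s$n)))))
write.table(conn, "results/connectivity_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Pooled connectivity (mean +/- SD per group and state):")
print(conn, row.names = FALSE)

# representative edge list (group A, state A) at the configured threshold
grpA <- prepped$A; ftA <- fits$A
segA <- backfit(ftA$model, grpA[[1]]$clean, ftA$gfps[[1]])
sdA <- extract_state_data(grpA[[1]]$clean, segA, 1, gfp = ftA$gfps[[1]],
                          align_to = ftA$model, remove_span = TRUE)
cmA <- pearson_connectivity(parcellate(apply_inverse(inv, sdA$data),
                                       cohort$parcellation), "A")
edges <- threshold_edges(cmA, cfg$edge_threshold)
write.table(edges, "results/edges_A01_stateA.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("Example edge list: %d edges at |r| >= %.2f for subject A01, state A",
                nrow(edges), cfg$edge_threshold))
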