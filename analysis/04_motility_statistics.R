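#!/usr/bin/env Rscript
# Motility read-outs of the synthetic experiments: motile fraction,
# velocity components and modulus, cumulative chemotactic index, and the
# biased-cell percentages; plus figures regenerated purely from the CSVs.

suppressPackageStartupMessages(library(gradchamber))
dir.create("results", showWarnings = FALSE)

profiles <- c("donorA", "donorB", "isotropic")
reports <- list()
for (slug in profiles) {
  path <- sprintf("scratch/tracks_%s.csv", slug)
  tracks <- if (file.exists(path)) read_tracks(path) else
    make_fixture_experiment(
      c(donorA = "donorA-like", donorB = "donorB-like",
        isotropic = "isotropic")[[slug]], seed = 30)$tracks
  rep <- motility_report(tracks)
  rep$profile <- slug
  write.csv(rep, sprintf("results/motility_%s.csv", slug), row.names = FALSE)
  reports[[slug]] <- rep

  ci <- rep[rep$metric == "chemotactic_index", ]
  mf <- rep[rep$metric == "motile_fraction", ]
  sp <- per_cell_mean_speed(tracks)
  ssum <- attr(sp, "summary")
  cat(sprintf(
    "%-9s: I pre %.2f -> post end %.2f (peak %.2f); motile %2.0f%% -> %2.0f%%; speed %.2f -> %.2f um/min\n",
    slug, mean(ci$value[ci$bin_start <= 30]), ci$value[nrow(ci)],
    max(ci$value[ci$bin_start > 30]),
    100 * mean(mf$value[mf$bin_start < 30]),
    100 * mean(mf$value[mf$bin_start >= 40]),
    ssum$mean[ssum$period == "pre"], ssum$mean[ssum$period == "post"]))

  # pre/post per-cell speed histograms (1 um/min bins)
  h_pre <- speed_histogram(sp$pre); h_pre$period <- "pre"
  h_post <- speed_histogram(sp$post); h_post$period <- "post"
  write.csv(rbind(h_pre, h_post),
            sprintf("results/speed_histogram_%s.csv", slug),
            row.names = FALSE)
}

# figures, rebuilt from the written CSVs alone
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("scratch/figures", showWarnings = FALSE)
  all <- do.call(rbind, lapply(profiles, function(s)
    read.csv(sprintf("results/motility_%s.csv", s))))
  for (m in c("chemotactic_index", "motile_fraction", "v_y", "v_mod")) {
    p <- ggplot(subset(all, metric == m),
                aes(bin_start, value, colour = profile)) +
      geom_line() + geom_vline(xintercept = 30, linetype = 2) +
      labs(x = "time (min)", y = m,
           title = sprintf("%s vs time (stimulus at 30 min)", m)) +
      theme_minimal()
    ggsave(sprintf("scratch/figures/%s.pdf", m), p, width = 6, height = 4)
  }
  cat("figures written under scratch/figures/\n")
}
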