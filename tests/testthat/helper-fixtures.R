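# Shared fixtures and independent oracles. Oracles are deliberately naive
# re-derivations (step-up loops, tail enumeration, textbook formulas) kept
# separate from the package's implementations.

make_profile <- function(fc, genes = sprintf("g%03d", seq_along(fc)),
                         p = NULL,
                         condition = list(platform = "in_vivo", dose = "high",
                                          time = "t1")) {
  df <- data.frame(gene_id = genes, log2_fc = fc, stringsAsFactors = FALSE)
  if (!is.null(p)) {
    df$p_value <- p
    df$q_value <- bh_adjust(p)
  }
  structure(df, condition = condition, genes_tested = nrow(df),
            n_dropped = 0L, class = c("fold_change_profile", "data.frame"))
}

# Textbook Benjamini-Hochberg step-up, written independently of p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Exact upper-tail hypergeometric P(X >= k) by summing the mass function.
hyper_tail_oracle <- function(k, pathway_size, universe_size, list_size) {
  kk <- k:min(pathway_size, list_size)
  sum(stats::dhyper(kk, pathway_size, universe_size - pathway_size, list_size))
}

# Pearson correlation from the definition.
pearson_oracle <- function(x, y) {
  xd <- x - mean(x); yd <- y - mean(y)
  sum(xd * yd) / sqrt(sum(xd^2) * sum(yd^2))
}

# One-platform, one- or two-dose simulation used across tests.
small_design <- function(n_genes, seed, doses = c(control = 0, low = 1),
                         times = c(t1 = 1), noise_sd = 0.5,
                         n_control = 3, n_treated = 3) {
  simulation_design(n_genes = n_genes, platforms = "vivo", doses = doses,
                    times = times, n_control = n_control,
                    n_treated = n_treated, noise_sd = noise_sd, seed = seed)
}

table4_fixture <- function() {
  path <- system.file("extdata", "table4_module_zscores.tsv",
                      package = "toxmod")
  utils::read.delim(path, check.names = FALSE)
}
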