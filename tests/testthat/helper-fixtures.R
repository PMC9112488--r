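# Small in-code fixtures shared across test files.

# proteins x samples QuantMatrix from a bare matrix
toy_quant <- function(x, groups, scale = "log2", mw = NULL,
                      is_histone = NULL, extra_samples = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  proteins <- data.frame(
    protein_id = sprintf("P%03d", seq_len(n)),
    gene_name = sprintf("G%03d", seq_len(n)),
    mw_da = if (is.null(mw)) rep(5e4, n) else mw,
    is_histone = if (is.null(is_histone)) rep(FALSE, n) else is_histone,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(ncol(x))),
                        group = groups, stringsAsFactors = FALSE)
  if (!is.null(extra_samples)) samples <- cbind(samples, extra_samples)
  quant_matrix(x, proteins, samples, scale = scale)
}

# DetectionMatrix built directly from counts
toy_detection <- function(n_detected, n_replicates) {
  n_detected <- as.matrix(n_detected)
  structure(list(
    n_detected = matrix(n_detected, nrow = nrow(n_detected),
                        dimnames = list(
                          sprintf("P%03d", seq_len(nrow(n_detected))),
                          names(n_replicates))),
    n_replicates = n_replicates,
    protein_ids = sprintf("P%03d", seq_len(nrow(n_detected)))
  ), class = "DetectionMatrix")
}

# independent hypergeometric tail oracle via binomial coefficients
hyper_tail_oracle <- function(x, K, N, n) {
  js <- seq(x, min(K, n))
  if (!length(js) || x > min(K, n)) return(if (x <= 0) 1 else 0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# CopyTable wrapper around a plain mass/copies matrix (for composition ops)
toy_copy_table <- function(mass, copies = mass) {
  mass <- as.matrix(mass)
  structure(list(
    copies_per_cell = as.matrix(copies),
    mass_per_cell_pg = mass,
    totals = data.frame(sample_id = colnames(mass),
                        total_copies = colSums(copies, na.rm = TRUE),
                        total_mass_pg = colSums(mass, na.rm = TRUE)),
    samples = data.frame(sample_id = colnames(mass),
                         group = colnames(mass),
                         stringsAsFactors = FALSE),
    proteins = data.frame(protein_id = rownames(mass),
                          stringsAsFactors = FALSE),
    constants = ruler_constants()
  ), class = "CopyTable")
}
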