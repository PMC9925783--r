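# Small shared fixtures, built in code.

small_atlas <- function(n_rois = 60, seed = 101) {
  generate_atlas(atlas_spec(n_rois = n_rois), seed = seed)
}

# a tiny deterministic two-class pattern set: go mixtures activate ROIs 1-2,
# no-go mixtures activate ROIs 3-4 (negative z = activation)
toy_patterns <- function() {
  train <- rbind(
    c(-2.0, -1.5,  0.0,  0.0, -0.3),
    c(-1.8, -1.6,  0.0,  0.0, -0.2),
    c( 0.0,  0.0, -2.1, -1.4, -0.3),
    c( 0.0,  0.0, -1.9, -1.6, -0.2)
  )
  colnames(train) <- paste0("roi_", 1:5)
  list(train = train, labels = c("go", "go", "nogo", "nogo"))
}

# independent re-evaluation of the saturating sigmoid, spreadsheet style
sat_formula <- function(r_o, A, s) 2 * A / (1 + exp(r_o * s)) - A

# all-pairs auROC oracle (ties get half credit)
auroc_pairs <- function(values, is_go) {
  pos <- values[is_go]
  neg <- values[!is_go]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# nested grid-search minimizer of the two-element deconvolution cost
lasso_cost <- function(c_vec, D, s, lambda) {
  sum((s - D %*% c_vec)^2) + lambda * sum(abs(c_vec))
}

grid_search_lasso2 <- function(D, s, lambda, lo = -3, hi = 3) {
  best <- c(0, 0)
  width <- hi - lo
  center <- c(0, 0)
  for (level in 1:5) {
    g <- seq(-width / 2, width / 2, length.out = 41)
    vals <- expand.grid(c1 = center[1] + g, c2 = center[2] + g)
    costs <- apply(vals, 1, function(v) lasso_cost(v, D, s, lambda))
    best <- as.numeric(vals[which.min(costs), ])
    center <- best
    width <- width / 10
  }
  best
}
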