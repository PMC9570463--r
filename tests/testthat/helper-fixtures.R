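# Shared fixtures: all test data is generated in code at run time.

random_windows <- function(n, L = 41L, seed = 1L) {
  m6amnet:::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# A tiny base-classifier spec that trains in seconds.
tiny_spec <- function(...) {
  defaults <- list(attention_heads = 2L, attention_model_dim = 8L,
                   conv1_filters = 8L, conv1_kernel = 5L,
                   conv2_filters = 8L, conv2_kernel = 3L,
                   pool_size = 2L, lstm_hidden = 8L,
                   branch_fc_dim = 8L, head_fc_dims = c(8L, 2L),
                   dropout_rates = c(0.2, 0.2), max_epochs = 6L,
                   patience = 3L, seed = 7L)
  do.call(base_classifier_spec, utils::modifyList(defaults, list(...)))
}

small_synthetic <- function(n_per_class = 120L, lambda = 0.9, seed = 3L,
                            n_chromosomes = 4L) {
  generate_synthetic_dataset(synthetic_spec(
    n_per_class = n_per_class, signal_strength = lambda,
    n_chromosomes = n_chromosomes, seed = seed))
}

# Cheap reference model for protocol tests: per-position naive Bayes on
# one-hot counts (Laplace-smoothed log-odds), trained in milliseconds.
nb_recipe <- function(train_ds, seed) {
  M <- m6amnet:::seqs_to_int_matrix(train_ds$records$window)
  y <- train_ds$records$label
  L <- ncol(M)
  logodds <- matrix(0, L, 4)
  for (b in 1:4) {
    p1 <- (colSums(M[y == 1L, , drop = FALSE] == b) + 1) / (sum(y == 1L) + 4)
    p0 <- (colSums(M[y == 0L, , drop = FALSE] == b) + 1) / (sum(y == 0L) + 4)
    logodds[, b] <- log(p1 / p0)
  }
  function(windows) {
    Mq <- m6amnet:::seqs_to_int_matrix(unname(windows))
    s <- vapply(seq_len(nrow(Mq)), function(i) {
      sum(logodds[cbind(seq_len(L), Mq[i, ])])
    }, numeric(1))
    1 / (1 + exp(-s))
  }
}

# Candidate pool assembled by hand (for ensemble-algebra tests that do not
# need trained members).
fake_pool <- function(specs, accs) {
  stopifnot(length(specs) == length(accs))
  entries <- lapply(seq_along(specs), function(i) {
    m <- build_base_classifier(specs[[i]])
    m$trained <- TRUE
    m$validation_acc <- accs[i]
    list(spec = specs[[i]], model = m, validation_acc = accs[i],
         grid_index = i)
  })
  entries <- entries[order(-accs, seq_along(accs))]
  structure(entries, class = "candidate_pool")
}

# Benchmark-shaped chromosome counts (positives, negatives) used by the
# hold-out grouping tests: 18 chromosomes with both classes >= 50 and five
# small ones expected to pool.
benchmark_chrom_counts <- function() {
  data.frame(
    chromosome = c("chr1", "chr2", "chr3", "chr4", "chr5", "chr6", "chr7",
                   "chr8", "chr9", "chr10", "chr11", "chr12", "chr13",
                   "chr14", "chr15", "chr16", "chr17", "chr18", "chr19",
                   "chr20", "chr21", "chr22", "chrX"),
    positive = c(191, 115, 100, 64, 80, 94, 92, 52, 69, 72, 108, 93, 32,
                 72, 71, 64, 109, 16, 108, 37, 18, 26, 91),
    negative = c(197, 115, 108, 65, 72, 101, 93, 57, 66, 71, 94, 101, 39,
                 83, 66, 61, 107, 18, 99, 44, 22, 23, 72),
    stringsAsFactors = FALSE)
}

# Dataset with given per-chromosome class counts; windows are irrelevant
# to split logic, so a fixed valid BCA window is reused.
counts_dataset <- function(counts) {
  win <- paste0(strrep("G", 18), "GCA", strrep("G", 20))
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    with(counts[i, ], data.frame(
      chromosome = chromosome,
      label = rep(c(1L, 0L), c(positive, negative)),
      stringsAsFactors = FALSE))
  }))
  rows$position <- seq_len(nrow(rows)) * 50L
  rows$strand <- "+"
  rows$window <- win
  rows$record_id <- sprintf("%s:%d:+:%d", rows$chromosome, rows$position,
                            rows$label)
  m6amnet:::new_m6am_dataset(
    rows[, c("record_id", "chromosome", "position", "strand", "label",
             "window")], flank = 20L)
}

# Finite-difference gradient of the full-model loss wrt sampled entries.
check_grads <- function(model, Xm, n, y, n_entries = 4L, eps = 1e-5,
                        seed = 99L) {
  res <- m6amnet:::nn_loss_grads(model, Xm, n, y, train = FALSE)
  worst <- 0
  m6amnet:::with_seed(seed, {
    for (mod in names(model$params)) {
      for (nm in names(model$params[[mod]])) {
        P <- model$params[[mod]][[nm]]
        G <- res$grads[[mod]][[nm]]
        if (!is.numeric(P) || is.null(G)) next
        for (ii in sample(length(P), min(n_entries, length(P)))) {
          m2 <- model
          m2$params[[mod]][[nm]][ii] <- P[ii] + eps
          lp <- m6amnet:::nn_loss_grads(m2, Xm, n, y, train = FALSE)$loss
          m2$params[[mod]][[nm]][ii] <- P[ii] - eps
          lm <- m6amnet:::nn_loss_grads(m2, Xm, n, y, train = FALSE)$loss
          num <- (lp - lm) / (2 * eps)
          rel <- abs(num - G[ii]) / max(1e-6, abs(num) + abs(G[ii]))
          worst <- max(worst, rel)
        }
      }
    }
  })
  worst
}
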