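# Planted-motif synthetic benchmark generator. Emulates the shape of the
# real benchmark (41-nt windows, center A in a BCA context, balanced
# classes, pseudo-chromosome provenance) with a controllable class signal:
# a fraction lambda of positives carry a position weight matrix planted at
# a fixed offset from the center. The BCA context is imposed on BOTH
# classes so the class signal is solely the planted motif.

#' Position weight matrix from a consensus string
#'
#' @param consensus RNA string; each position becomes a deterministic
#'   column.
#' @return 4 x nchar(consensus) column-stochastic matrix, rows A,C,G,U.
#' @export
consensus_pwm <- function(consensus) {
  idx <- seq_to_int(normalize_sequence(consensus))
  m <- matrix(0, 4, length(idx), dimnames = list(RNA_BASES, NULL))
  m[cbind(idx, seq_along(idx))] <- 1
  m
}

#' Specification of a synthetic benchmark dataset
#'
#' Defaults state the world the generator emulates: 2,000 windows per
#' class of length 41, uniform background composition, a deterministic
#' 6-mer motif planted 3 nt downstream of the center in 90% of positives,
#' and 8 pseudo-chromosomes (enough records per chromosome for hold-out
#' protocols).
#'
#' @param n_per_class windows per class.
#' @param window_length odd window length (default 41).
#' @param background length-4 base probabilities (A,C,G,U), summing to 1.
#' @param motif 4 x w column-stochastic PWM (rows A,C,G,U), e.g. from
#'   [consensus_pwm()].
#' @param motif_offset start of the motif relative to the center (0 = the
#'   center A); the motif must not overlap the fixed (B,C,A) context at
#'   offsets -2..0.
#' @param signal_strength fraction lambda of positives carrying the motif.
#' @param n_chromosomes number of pseudo-chromosome labels, assigned
#'   round-robin within each class.
#' @param seed integer seed; identical specs yield byte-identical output.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 2000L, window_length = 41L,
                           background = c(0.25, 0.25, 0.25, 0.25),
                           motif = consensus_pwm("CUGGAC"),
                           motif_offset = 3L,
                           signal_strength = 0.9,
                           n_chromosomes = 8L,
                           seed = 1L) {
  stopifnot(window_length %% 2L == 1L, window_length >= 7L,
            n_per_class >= 1L, n_chromosomes >= 1L)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-8 ||
      any(background < 0)) {
    stop("background must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (!is.matrix(motif) || nrow(motif) != 4L ||
      any(abs(colSums(motif) - 1) > 1e-8) || any(motif < 0)) {
    stop("motif must be a 4 x w column-stochastic matrix", call. = FALSE)
  }
  if (signal_strength < 0 || signal_strength > 1) {
    stop("signal_strength must be in [0, 1]", call. = FALSE)
  }
  w <- ncol(motif)
  cover <- motif_offset + seq_len(w) - 1L  # offsets relative to center
  if (any(cover %in% c(-2L, -1L, 0L))) {
    stop("motif overlaps the fixed (B,C,A) center context at offsets -2..0",
         call. = FALSE)
  }
  flank <- (window_length - 1L) %/% 2L
  if (min(cover) < -flank || max(cover) > flank) {
    stop("motif extends beyond the window", call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 window_length = as.integer(window_length),
                 background = as.numeric(background),
                 motif = motif, motif_offset = as.integer(motif_offset),
                 signal_strength = signal_strength,
                 n_chromosomes = as.integer(n_chromosomes),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic benchmark dataset
#'
#' Negatives are background draws with the BCA center imposed; positives
#' are identical except that a fraction `signal_strength` carry the PWM at
#' its offset. Records are round-robin assigned pseudo-chromosome labels
#' within each class, so the signal is chromosome-independent by
#' construction. Fully reproducible under the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return an `m6am_dataset`.
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_per_class
  L <- spec$window_length
  c0 <- (L + 1L) %/% 2L
  with_seed(spec$seed, {
    draw_class <- function(n, planted_frac) {
      M <- matrix(sample.int(4L, n * L, replace = TRUE,
                             prob = spec$background),
                  n, L)
      # impose B (C/G/U, background-renormalized), C, A at center-2..center
      bprob <- spec$background[2:4]
      if (sum(bprob) <= 0) bprob <- rep(1 / 3, 3)
      M[, c0 - 2L] <- sample.int(3L, n, replace = TRUE,
                                 prob = bprob / sum(bprob)) + 1L
      M[, c0 - 1L] <- 2L
      M[, c0] <- 1L
      planted <- runif(n) < planted_frac
      if (any(planted)) {
        for (j in seq_len(ncol(spec$motif))) {
          col <- c0 + spec$motif_offset + j - 1L
          M[planted, col] <- sample.int(4L, sum(planted), replace = TRUE,
                                        prob = spec$motif[, j])
        }
      }
      M
    }
    Mpos <- draw_class(n, spec$signal_strength)
    Mneg <- draw_class(n, 0)
    to_windows <- function(M) {
      apply(M, 1, function(r) paste(RNA_BASES[r], collapse = ""))
    }
    chroms <- sprintf("pchr%d", seq_len(spec$n_chromosomes))
    mk <- function(M, label, tag) {
      wins <- to_windows(M)
      chrom <- rep_len(chroms, n)
      pos <- seq_len(n) * 100L
      data.frame(record_id = sprintf("%s:%d:+:%d", chrom, pos, label),
                 chromosome = chrom, position = pos, strand = "+",
                 label = label, window = wins, stringsAsFactors = FALSE)
    }
    recs <- rbind(mk(Mpos, 1L), mk(Mneg, 0L))
    new_m6am_dataset(recs, flank = (L - 1L) %/% 2L,
                     provenance = list(generator = "synthetic",
                                       spec = .spec_as_list(spec)))
  })
}

.spec_as_list <- function(spec) {
  list(n_per_class = spec$n_per_class, window_length = spec$window_length,
       background = spec$background,
       motif = apply(spec$motif, 2, function(x) as.numeric(x),
                     simplify = FALSE),
       motif_offset = spec$motif_offset,
       signal_strength = spec$signal_strength,
       n_chromosomes = spec$n_chromosomes, seed = spec$seed)
}

#' Background motif occurrence rate and achievable-signal bound
#'
#' For a deterministic-consensus motif the probability that a background
#' window carries the consensus at the planted offset is the product of
#' the background probabilities of the consensus letters; for a
#' non-deterministic PWM an interval (product of min/max background
#' probabilities over each column's support) is returned instead. The
#' expected positive-class motif frequency follows the mixture
#' `lambda + (1 - lambda) * background_rate`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `background_rate` (length 1, or length 2 `c(lo, hi)`
#'   for a non-deterministic PWM), `positive_rate` (same shape) and
#'   `deterministic` flag.
#' @export
estimate_bayes_gap <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  det <- all(apply(spec$motif, 2, max) == 1)
  lam <- spec$signal_strength
  if (det) {
    letters <- apply(spec$motif, 2, which.max)
    rate <- prod(spec$background[letters])
  } else {
    per_col <- apply(spec$motif, 2, function(col) {
      sup <- which(col > 0)
      range(spec$background[sup])
    })
    rate <- c(lo = prod(per_col[1, ]), hi = prod(per_col[2, ]))
  }
  list(background_rate = rate,
       positive_rate = lam + (1 - lam) * rate,
       deterministic = det)
}

#' Write a synthetic dataset with its spec sidecar
#'
#' Emits the same FASTA + TSV format as [write_benchmark_dataset()], plus
#' a YAML serialization of the generating spec.
#'
#' @param spec a [synthetic_spec()].
#' @param prefix output path prefix.
#' @return invisible named vector of written paths.
#' @export
write_synthetic_dataset <- function(spec, prefix) {
  ds <- generate_synthetic_dataset(spec)
  paths <- write_benchmark_dataset(ds, prefix)
  yml <- paste0(prefix, ".spec.yaml")
  yaml::write_yaml(.spec_as_list(spec), yml)
  invisible(c(paths, spec = yml))
}

#' Read a synthetic spec from YAML
#'
#' @param path YAML file written by [write_synthetic_dataset()] (or
#'   hand-authored with the same keys).
#' @return a [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  motif <- if (!is.null(y$motif)) {
    do.call(cbind, lapply(y$motif, as.numeric))
  } else {
    consensus_pwm(y$consensus)
  }
  rownames(motif) <- RNA_BASES
  synthetic_spec(n_per_class = y$n_per_class %||% 2000L,
                 window_length = y$window_length %||% 41L,
                 background = y$background %||% rep(0.25, 4),
                 motif = motif,
                 motif_offset = y$motif_offset %||% 3L,
                 signal_strength = y$signal_strength %||% 0.9,
                 n_chromosomes = y$n_chromosomes %||% 8L,
                 seed = y$seed %||% 1L)
}
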