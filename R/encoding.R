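# Context-based encoders. Each maps a validated RNA string of length L to
# an L x C numeric matrix with labeled channels; channel values lie in [0,1].

# NCP channel semantics (one row per base, channel order fixed):
#   ring:     1 for purines (A,G), 0 for pyrimidines (C,U)
#   func:     1 for amino group (A,C), 0 for keto (G,U)
#   hbond:    1 for weak pairing (A,U), 0 for strong (C,G)
NCP_TABLE <- matrix(
  c(1, 1, 1,   # A
    0, 1, 0,   # C
    1, 0, 0,   # G
    0, 0, 1),  # U
  nrow = 4, byrow = TRUE,
  dimnames = list(RNA_BASES, c("ring", "func", "hbond"))
)

#' One-hot (binary) encoding
#'
#' Each residue becomes a 4-bit indicator row in fixed channel order
#' A, C, G, U, so a 41-nt window becomes a 41 x 4 matrix whose rows each
#' sum to 1.
#'
#' @param seq validated RNA string (see [normalize_sequence()]).
#' @return L x 4 numeric matrix, columns `A,C,G,U`.
#' @export
encode_one_hot <- function(seq) {
  idx <- seq_to_int(normalize_sequence(seq))
  m <- matrix(0, nrow = length(idx), ncol = 4,
              dimnames = list(NULL, RNA_BASES))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Nucleotide chemical property (NCP) encoding
#'
#' Three binary channels per residue: ring structure (purine vs
#' pyrimidine), chemical functionality (amino vs keto) and hydrogen-bond
#' strength (weak A:U vs strong C:G). The four bases map to distinct 3-bit
#' codes: A=(1,1,1), C=(0,1,0), G=(1,0,0), U=(0,0,1).
#'
#' @inheritParams encode_one_hot
#' @return L x 3 numeric matrix, columns `ring,func,hbond`.
#' @export
encode_ncp <- function(seq) {
  idx <- seq_to_int(normalize_sequence(seq))
  m <- NCP_TABLE[idx, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Nucleotide density (ND / accumulated nucleotide frequency) encoding
#'
#' Entry i is the count of occurrences of residue i's own letter among
#' positions 1..i, divided by i (1-based). For "ACGACUUAGA" this yields
#' (1, 1/2, 1/3, 2/4, 2/5, 1/6, 2/7, 3/8, 2/9, 4/10). Values lie in
#' (0, 1].
#'
#' @inheritParams encode_one_hot
#' @return L x 1 numeric matrix, column `nd`.
#' @export
encode_nd <- function(seq) {
  idx <- seq_to_int(normalize_sequence(seq))
  L <- length(idx)
  v <- numeric(L)
  cnt <- integer(4)
  for (i in seq_len(L)) {
    cnt[idx[i]] <- cnt[idx[i]] + 1L
    v[i] <- cnt[idx[i]] / i
  }
  matrix(v, ncol = 1, dimnames = list(NULL, "nd"))
}

.ENCODERS <- list(one_hot = encode_one_hot, ncp = encode_ncp, nd = encode_nd)
.ENCODER_CHANNELS <- c(one_hot = 4L, ncp = 3L, nd = 1L)

#' Define a feature scheme (ordered encoder fusion)
#'
#' @param encoders character vector, ordered subset of
#'   `c("one_hot", "ncp", "nd")`.
#' @return object of class `feature_scheme` with the encoder order and
#'   total channel count (4 + 3 + 1 = 8 for the default fusion).
#' @export
feature_scheme <- function(encoders = c("one_hot", "ncp", "nd")) {
  if (length(encoders) == 0) stop("scheme must name at least one encoder",
                                  call. = FALSE)
  unknown <- setdiff(encoders, names(.ENCODERS))
  if (length(unknown)) {
    stop(sprintf("unknown encoder(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(encoders)) stop("duplicated encoder in scheme",
                                    call. = FALSE)
  structure(list(encoders = encoders,
                 total_channels = sum(.ENCODER_CHANNELS[encoders])),
            class = "feature_scheme")
}

#' Fusion encoding: channel-wise concatenation of encoders
#'
#' Per-position concatenation in scheme order; the default scheme
#' `one_hot + ncp + nd` turns a 41-nt window into a 41 x 8 matrix.
#' Slicing the channel blocks of the result reproduces each standalone
#' encoder exactly.
#'
#' @inheritParams encode_one_hot
#' @param scheme a [feature_scheme()].
#' @return L x `scheme$total_channels` numeric matrix.
#' @export
encode_fusion <- function(seq, scheme = feature_scheme()) {
  if (!inherits(scheme, "feature_scheme")) scheme <- feature_scheme(scheme)
  do.call(cbind, lapply(scheme$encoders, function(e) .ENCODERS[[e]](seq)))
}

#' Encode many windows into a 3-D feature array
#'
#' Vectorized bulk version of [encode_fusion()] used on the model path;
#' agreement with the per-sequence encoders is property-tested.
#'
#' @param windows character vector of equal-length normalized RNA windows.
#' @param scheme a [feature_scheme()].
#' @return numeric array `n x L x C` with channel dimnames.
#' @export
encode_windows <- function(windows, scheme = feature_scheme()) {
  if (!inherits(scheme, "feature_scheme")) scheme <- feature_scheme(scheme)
  n <- length(windows)
  stopifnot(n > 0)
  M <- seqs_to_int_matrix(windows)
  L <- ncol(M)
  blocks <- list()
  for (e in scheme$encoders) {
    if (e == "one_hot") {
      a <- array(0, c(n, L, 4))
      idx <- cbind(rep(seq_len(n), L), rep(seq_len(L), each = n), as.vector(M))
      a[idx] <- 1
      dimnames(a) <- list(NULL, NULL, RNA_BASES)
    } else if (e == "ncp") {
      a <- array(NCP_TABLE[as.vector(M), ], c(n, L, 3))
      dimnames(a) <- list(NULL, NULL, colnames(NCP_TABLE))
    } else { # nd: prefix counts via cumulative indicator sums
      tri <- upper.tri(matrix(0, L, L), diag = TRUE) * 1  # s<=t
      nd <- matrix(0, n, L)
      for (b in 1:4) {
        ind <- (M == b) * 1
        nd <- nd + ind * (ind %*% tri)
      }
      nd <- sweep(nd, 2, seq_len(L), "/")
      a <- array(nd, c(n, L, 1))
      dimnames(a) <- list(NULL, NULL, "nd")
    }
    blocks[[e]] <- a
  }
  C <- scheme$total_channels
  out <- array(0, c(n, L, C))
  labels <- character(C)
  at <- 0L
  for (e in scheme$encoders) {
    w <- dim(blocks[[e]])[3]
    out[, , (at + 1L):(at + w)] <- blocks[[e]]
    labels[(at + 1L):(at + w)] <- dimnames(blocks[[e]])[[3]]
    at <- at + w
  }
  dimnames(out) <- list(names(windows), NULL, labels)
  out
}

#' Export encoded matrices to TSV for inspection
#'
#' Writes one TSV per record (positions as rows, labeled channels as
#' columns).
#'
#' @param windows named character vector of windows.
#' @param dir output directory.
#' @param scheme a [feature_scheme()].
#' @return invisible character vector of written paths.
#' @export
export_encodings <- function(windows, dir, scheme = feature_scheme()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(windows) %||% paste0("record", seq_along(windows))
  paths <- character(length(windows))
  for (i in seq_along(windows)) {
    m <- encode_fusion(windows[[i]], scheme)
    df <- data.frame(position = seq_len(nrow(m)), m, check.names = FALSE)
    paths[i] <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", ids[i]),
                                      ".tsv"))
    write.table(df, paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
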