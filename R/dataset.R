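# Benchmark dataset construction: window extraction around candidate
# adenosines, BCA-motif filtering, redundancy removal, balanced negative
# sampling and split planning.
#
# Coordinate conventions: site positions are 0-based (BED-style) on input;
# windows are reported 5'->3' on the transcript strand, so minus-strand
# sites are reverse-complemented before T->U normalization.

new_m6am_dataset <- function(records, flank, provenance = list()) {
  stopifnot(is.data.frame(records),
            all(c("record_id", "chromosome", "position", "strand",
                  "label", "window") %in% names(records)))
  structure(list(records = records, flank = as.integer(flank),
                 provenance = provenance),
            class = "m6am_dataset")
}

#' @export
print.m6am_dataset <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<m6am_dataset> %d records (%d positive / %d negative), window %d nt\n",
              n, sum(x$records$label == 1L), sum(x$records$label == 0L),
              2L * x$flank + 1L))
  invisible(x)
}

#' Read a site list from TSV or BED6
#'
#' TSV input needs a header with columns `chromosome` (or `chrom`),
#' `position` (0-based coordinate of the candidate A), `strand` and
#' optionally `label`. `.bed` input is headerless BED6
#' (chrom, start, end, name, score, strand); `start` is the site position
#' and `name` supplies the label (`positive`/`negative`/`1`/`0`,
#' default candidate).
#'
#' @param path file path; BED parsing is triggered by a `.bed` extension.
#' @return data.frame with columns chromosome, position, strand, label.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop(sprintf("site file not found: %s", path),
                               call. = FALSE)
  if (tolower(tools::file_ext(path)) == "bed") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("BED input must have 6 columns", call. = FALSE)
    names(df)[1:6] <- c("chromosome", "start", "end", "name", "score", "strand")
    lab <- tolower(as.character(df$name))
    label <- ifelse(lab %in% c("positive", "1"), "positive",
                    ifelse(lab %in% c("negative", "0"), "negative", "candidate"))
    out <- data.frame(chromosome = df$chromosome, position = df$start,
                      strand = df$strand, label = label,
                      stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    names(df)[names(df) == "chrom"] <- "chromosome"
    names(df)[names(df) == "pos"] <- "position"
    need <- c("chromosome", "position", "strand")
    if (!all(need %in% names(df))) {
      stop(sprintf("site TSV must have columns %s", paste(need, collapse = ", ")),
           call. = FALSE)
    }
    out <- df[, c(need, intersect("label", names(df))), drop = FALSE]
    if (is.null(out$label)) out$label <- "candidate"
  }
  if (!all(out$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  out
}

#' Extract a centered window around a genomic site
#'
#' Returns the (2*flank + 1)-nt window centered on the candidate A.
#' Minus-strand sites are reverse-complemented before T->U normalization so
#' the window reads 5'->3' on the transcript strand. Windows overlapping a
#' sequence end are an error (no padding rule is applied), as is a
#' non-adenosine center after strand handling.
#'
#' @param reference named character vector (or single named sequence) of
#'   chromosome/transcript sequences, DNA or RNA alphabet.
#' @param site list or one-row data.frame with `chromosome`, `position`
#'   (0-based coordinate of the candidate A), `strand`, optional `label`.
#' @param flank flank size xi; the window spans `2*flank + 1` nt
#'   (default 20, i.e. 41-nt windows).
#' @return one-row data.frame (a sample record) with the normalized window.
#' @export
extract_window <- function(reference, site, flank = 20L) {
  stopifnot(flank >= 1L)
  chrom <- as.character(site$chromosome)
  pos <- as.integer(site$position)
  strand <- as.character(site$strand)
  if (!chrom %in% names(reference)) {
    stop(sprintf("chromosome '%s' not in reference", chrom), call. = FALSE)
  }
  ref <- reference[[chrom]]
  L <- nchar(ref)
  lo <- pos + 1L - flank
  hi <- pos + 1L + flank
  if (lo < 1L || hi > L) {
    stop(sprintf("window out of bounds for site %s:%d:%s (need %d..%d on a %d-nt sequence)",
                 chrom, pos, strand, lo, hi, L), call. = FALSE)
  }
  win <- substr(ref, lo, hi)
  if (strand == "-") win <- reverse_complement(win)
  win <- normalize_sequence(win)
  center <- substr(win, flank + 1L, flank + 1L)
  if (center != "A") {
    stop(sprintf("center residue is '%s', not A, for site %s:%d:%s",
                 center, chrom, pos, strand), call. = FALSE)
  }
  lab <- as.character(site$label %||% "candidate")
  data.frame(record_id = sprintf("%s:%d:%s:%s", chrom, pos, strand,
                                 .label_code(lab)),
             chromosome = chrom, position = pos, strand = strand,
             label = .label_int(lab), window = win,
             stringsAsFactors = FALSE)
}

.label_code <- function(label) {
  switch(label, positive = "1", negative = "0", label)
}
.label_int <- function(label) {
  if (label %in% c("positive", "1")) 1L
  else if (label %in% c("negative", "0")) 0L
  else NA_integer_
}

#' Test the BCA center context
#'
#' TRUE iff the center residue is A, the residue immediately 5' of it is C,
#' and the residue two positions 5' is B in \{C, G, U\} (i.e. not A).
#'
#' @param window RNA window string (odd length >= 5) or a record
#'   data.frame with a `window` column (vectorized over rows).
#' @return logical vector.
#' @export
has_bca_center <- function(window) {
  if (is.data.frame(window)) window <- window$window
  vapply(window, function(w) {
    L <- nchar(w)
    c0 <- (L + 1L) %/% 2L
    if (L < 5L || L %% 2L == 0L) stop("window must have odd length >= 5",
                                      call. = FALSE)
    substr(w, c0, c0) == "A" &&
      substr(w, c0 - 1L, c0 - 1L) == "C" &&
      substr(w, c0 - 2L, c0 - 2L) %in% c("C", "G", "U")
  }, logical(1), USE.NAMES = FALSE)
}

#' Remove redundant windows by greedy identity clustering
#'
#' Greedy single-pass clustering in input order: a window joins the cluster
#' of the first earlier-retained window with global identity >= the
#' threshold, otherwise founds a new cluster; cluster founders are
#' retained. The internal backend computes identity as matches/length over
#' the equal-length windows. The `cd-hit-est` backend shells out to the
#' CD-HIT-EST binary when available and parses its `.clstr` output.
#'
#' @param x an `m6am_dataset` or a character vector of equal-length windows.
#' @param identity_threshold clustering threshold (default 0.8; the
#'   external backend's nucleotide floor requires >= 0.8 and < 1).
#' @param backend `"internal"` or `"cd-hit-est"`.
#' @return object of the same type as `x`, reduced to retained records.
#' @export
redundancy_filter <- function(x, identity_threshold = 0.8,
                              backend = c("internal", "cd-hit-est")) {
  backend <- match.arg(backend)
  windows <- if (inherits(x, "m6am_dataset")) x$records$window else x
  if (length(windows) == 0) stop("no records to filter", call. = FALSE)
  if (backend == "cd-hit-est") {
    if (identity_threshold < 0.8 || identity_threshold >= 1) {
      stop("cd-hit-est supports nucleotide identity thresholds in [0.8, 1)",
           call. = FALSE)
    }
    keep <- .cdhit_retained(windows, identity_threshold)
  } else {
    keep <- .greedy_identity_retained(windows, identity_threshold)
  }
  if (inherits(x, "m6am_dataset")) {
    prov <- x$provenance
    prov$redundancy <- list(threshold = identity_threshold, backend = backend,
                            dropped = length(windows) - length(keep))
    new_m6am_dataset(x$records[keep, , drop = FALSE], x$flank, prov)
  } else {
    x[keep]
  }
}

.greedy_identity_retained <- function(windows, threshold) {
  M <- seqs_to_int_matrix(windows)
  L <- ncol(M)
  keep <- integer(0)
  for (i in seq_len(nrow(M))) {
    if (length(keep)) {
      ident <- rowMeans(M[keep, , drop = FALSE] ==
                          matrix(M[i, ], length(keep), L, byrow = TRUE))
      if (any(ident >= threshold)) next
    }
    keep <- c(keep, i)
  }
  keep
}

.cdhit_retained <- function(windows, threshold) {
  bin <- Sys.which("cd-hit-est")
  if (!nzchar(bin)) {
    stop("cd-hit-est binary not found on PATH; use backend = \"internal\"",
         call. = FALSE)
  }
  td <- tempfile("cdhit")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fa <- file.path(td, "in.fasta")
  ids <- sprintf("w%06d", seq_along(windows))
  write_fasta_sequences(setNames(chartr("U", "T", windows), ids), fa)
  out <- file.path(td, "out")
  status <- system2(bin, c("-i", fa, "-o", out, "-c", format(threshold),
                           "-n", "5", "-d", "0"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("cd-hit-est failed", call. = FALSE)
  clstr <- readLines(paste0(out, ".clstr"))
  reps <- sub("^.*>([^. ]+)\\.\\.\\..*$", "\\1", grep("\\*$", clstr, value = TRUE))
  sort(match(reps, ids))
}

#' Sample negatives uniformly without replacement
#'
#' @param candidates an `m6am_dataset` (or record data.frame) of candidate
#'   negative windows; all must pass [has_bca_center()].
#' @param n number of negatives to draw (typically the positive count, for
#'   a 1:1 class balance).
#' @param seed integer seed; the same seed reproduces the same selection.
#' @return same type as `candidates`, reduced to the sample (input order
#'   preserved).
#' @export
sample_negatives <- function(candidates, n, seed) {
  recs <- if (inherits(candidates, "m6am_dataset")) candidates$records
          else candidates
  if (n > nrow(recs)) {
    stop(sprintf("requested %d negatives but only %d candidates available",
                 n, nrow(recs)), call. = FALSE)
  }
  idx <- sort(with_seed(seed, sample.int(nrow(recs), n)))
  if (inherits(candidates, "m6am_dataset")) {
    new_m6am_dataset(recs[idx, , drop = FALSE], candidates$flank,
                     c(candidates$provenance, list(negative_seed = seed)))
  } else {
    recs[idx, , drop = FALSE]
  }
}

new_split_plan <- function(assignment, name, seed = NA_integer_,
                           fraction = NA_real_) {
  stopifnot(is.data.frame(assignment),
            all(c("record_id", "partition") %in% names(assignment)))
  structure(list(assignment = assignment, name = name,
                 seed = seed, fraction = fraction),
            class = "m6am_split_plan")
}

#' @export
print.m6am_split_plan <- function(x, ...) {
  tab <- table(x$assignment$partition)
  cat(sprintf("<m6am_split_plan '%s'> %s\n", x$name,
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Random train/test split
#'
#' Stratified by label by default: the global train size is
#' `round(fraction * n)` and is apportioned across classes by largest
#' remainder, so both partitions stay approximately balanced.
#'
#' @param dataset an `m6am_dataset`.
#' @param train_fraction fraction assigned to train (default 0.8).
#' @param seed integer seed.
#' @param stratified stratify by label (default TRUE; errors on a
#'   single-class dataset).
#' @return an `m6am_split_plan` with partitions `train` and `test`.
#' @export
train_test_split <- function(dataset, train_fraction = 0.8, seed,
                             stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  recs <- dataset$records
  n <- nrow(recs)
  target <- round(train_fraction * n)
  part <- rep("test", n)
  if (stratified) {
    classes <- sort(unique(recs$label))
    if (length(classes) < 2) {
      stop("stratified split needs both classes present", call. = FALSE)
    }
    sizes <- vapply(classes, function(cl) sum(recs$label == cl), integer(1))
    exact <- train_fraction * sizes
    take <- floor(exact)
    rem <- target - sum(take)
    if (rem > 0) {
      order_rem <- order(-(exact - take), seq_along(classes))
      take[order_rem[seq_len(rem)]] <- take[order_rem[seq_len(rem)]] + 1L
    }
    seeds <- derive_seeds(seed, length(classes))
    for (k in seq_along(classes)) {
      idx <- which(recs$label == classes[k])
      tr <- with_seed(seeds[k], sample(idx, min(take[k], length(idx))))
      part[tr] <- "train"
    }
  } else {
    tr <- with_seed(seed, sample.int(n, target))
    part[tr] <- "train"
  }
  new_split_plan(data.frame(record_id = recs$record_id, partition = part,
                            stringsAsFactors = FALSE),
                 name = "random", seed = seed, fraction = train_fraction)
}

#' Chromosome-level hold-out split plans
#'
#' One plan per chromosome with enough data (that chromosome = test, the
#' rest = train); all chromosomes below `min_count` are pooled into a
#' single final test group. With `count_mode = "per_class"` (default) a
#' chromosome qualifies when both its positive and negative counts reach
#' `min_count`; `"total"` counts all records.
#'
#' @param dataset an `m6am_dataset` with chromosome provenance.
#' @param min_count qualification threshold (default 50).
#' @param count_mode `"per_class"` or `"total"`.
#' @return list of `m6am_split_plan`, partitions `train`/`test`.
#' @export
chromosome_holdout_groups <- function(dataset, min_count = 50L,
                                      count_mode = c("per_class", "total")) {
  count_mode <- match.arg(count_mode)
  recs <- dataset$records
  if (any(is.na(recs$chromosome)) || !("chromosome" %in% names(recs))) {
    stop("records carry no chromosome metadata", call. = FALSE)
  }
  chroms <- unique(recs$chromosome)
  qual <- vapply(chroms, function(ch) {
    sub <- recs[recs$chromosome == ch, , drop = FALSE]
    if (count_mode == "total") nrow(sub) >= min_count
    else min(sum(sub$label == 1L), sum(sub$label == 0L)) >= min_count
  }, logical(1))
  plans <- lapply(chroms[qual], function(ch) {
    part <- ifelse(recs$chromosome == ch, "test", "train")
    new_split_plan(data.frame(record_id = recs$record_id, partition = part,
                              stringsAsFactors = FALSE),
                   name = paste0("holdout_", ch))
  })
  small <- chroms[!qual]
  if (length(small)) {
    part <- ifelse(recs$chromosome %in% small, "test", "train")
    plans <- c(plans, list(
      new_split_plan(data.frame(record_id = recs$record_id, partition = part,
                                stringsAsFactors = FALSE),
                     name = paste0("holdout_pooled_",
                                   paste(small, collapse = "+")))))
  }
  plans
}

#' Materialize a split plan into train/test datasets
#'
#' @param dataset an `m6am_dataset`.
#' @param plan an `m6am_split_plan`.
#' @return list with elements `train` and `test` (`m6am_dataset`s).
#' @export
split_dataset <- function(dataset, plan) {
  recs <- dataset$records
  part <- plan$assignment$partition[match(recs$record_id,
                                          plan$assignment$record_id)]
  stopifnot(!anyNA(part))
  lapply(list(train = "train", test = "test"), function(p) {
    new_m6am_dataset(recs[part == p, , drop = FALSE], dataset$flank,
                     c(dataset$provenance, list(split = plan$name)))
  })
}

#' Build a balanced benchmark dataset from a reference and site list
#'
#' Pipeline: extract windows for all sites (dropping out-of-bounds windows,
#' non-A centers and windows with ambiguity codes, with logged counts),
#' keep BCA-context windows, redundancy-filter positives and negative
#' candidates separately, then sample negatives 1:1 against the positives.
#'
#' @param reference named character vector of sequences (or FASTA path).
#' @param sites site data.frame (see [read_sites()]) with labels
#'   `positive` and `negative`/`candidate` (candidates feed the negative
#'   pool).
#' @param flank flank size xi (default 20).
#' @param identity_threshold redundancy threshold (default 0.8).
#' @param seed integer seed for negative sampling.
#' @param backend redundancy backend (see [redundancy_filter()]).
#' @param verbose log dropped-window counts to stderr.
#' @return an `m6am_dataset` with equal class counts.
#' @export
build_benchmark_dataset <- function(reference, sites, flank = 20L,
                                    identity_threshold = 0.8, seed = 1L,
                                    backend = "internal", verbose = TRUE) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- read_fasta_sequences(reference)
  }
  drops <- c(out_of_bounds = 0L, bad_center = 0L, invalid_alphabet = 0L,
             no_bca = 0L)
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    rec <- tryCatch(extract_window(reference, sites[i, ], flank),
                    error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      kind <- if (grepl("out of bounds", rec)) "out_of_bounds"
              else if (grepl("not A", rec)) "bad_center"
              else "invalid_alphabet"
      drops[kind] <- drops[kind] + 1L
      next
    }
    rows[[i]] <- rec
  }
  recs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(recs) || !nrow(recs)) stop("no extractable windows",
                                         call. = FALSE)
  bca <- has_bca_center(recs)
  drops["no_bca"] <- sum(!bca)
  recs <- recs[bca, , drop = FALSE]
  pos <- recs[!is.na(recs$label) & recs$label == 1L, , drop = FALSE]
  neg <- recs[is.na(recs$label) | recs$label == 0L, , drop = FALSE]
  neg$label <- 0L
  if (!nrow(pos)) stop("no positive windows survive filtering", call. = FALSE)
  pos <- .greedy_subset(pos, identity_threshold, backend)
  neg <- .greedy_subset(neg, identity_threshold, backend)
  if (nrow(neg) < nrow(pos)) {
    stop(sprintf("only %d negative candidates for %d positives",
                 nrow(neg), nrow(pos)), call. = FALSE)
  }
  neg <- sample_negatives(neg, nrow(pos), seed)
  msg("windows dropped: %s; retained %d positives + %d negatives",
      paste(sprintf("%s=%d", names(drops), drops), collapse = ", "),
      nrow(pos), nrow(neg), verbose = verbose)
  new_m6am_dataset(rbind(pos, neg), flank,
                   provenance = list(filters = as.list(drops),
                                     identity_threshold = identity_threshold,
                                     seed = seed))
}

.greedy_subset <- function(recs, threshold, backend) {
  keep <- if (backend == "internal") {
    .greedy_identity_retained(recs$window, threshold)
  } else {
    .cdhit_retained(recs$window, threshold)
  }
  recs[keep, , drop = FALSE]
}

#' Write a benchmark dataset as FASTA + companion TSV
#'
#' Record ids encode `chromosome:position:strand:label`; the TSV carries
#' the same metadata in columns.
#'
#' @param dataset an `m6am_dataset`.
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.tsv`.
#' @return invisible named character vector of the two paths.
#' @export
write_benchmark_dataset <- function(dataset, prefix) {
  recs <- dataset$records
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  dir.create(dirname(fa), recursive = TRUE, showWarnings = FALSE)
  write_fasta_sequences(setNames(recs$window, recs$record_id), fa)
  write.table(recs[, c("record_id", "chromosome", "position", "strand",
                       "label")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, tsv = tsv))
}

#' Read a benchmark dataset written by [write_benchmark_dataset()]
#'
#' @param prefix path prefix used at write time.
#' @return an `m6am_dataset`.
#' @export
read_benchmark_dataset <- function(prefix) {
  seqs <- read_fasta_sequences(paste0(prefix, ".fasta"))
  meta <- read.delim(paste0(prefix, ".tsv"), stringsAsFactors = FALSE,
                     colClasses = c(record_id = "character",
                                    chromosome = "character"))
  stopifnot(setequal(meta$record_id, names(seqs)))
  meta$window <- unname(seqs[meta$record_id])
  L <- nchar(meta$window[1])
  new_m6am_dataset(meta[, c("record_id", "chromosome", "position", "strand",
                            "label", "window")],
                   flank = (L - 1L) %/% 2L,
                   provenance = list(source = prefix))
}
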