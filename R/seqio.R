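# Readers and writers: samtools text pileup (read), depth-chart TSV
# (read/write), minimal VCF 4.2 (write), and the JSON estimate container
# used by the command-line interface.
#
# Depth-chart dialect: tab-delimited with header "chrom pos ref A C G T",
# 1-based positions, strand-insensitive pooled counts.

DEPTH_CHART_COLS <- c("chrom", "pos", "ref", "A", "C", "G", "T")

#' Read a samtools text pileup
#'
#' Parses the classic 6-column text pileup (chrom, 1-based position,
#' reference base, depth, read bases, base qualities) into per-base
#' counts. In the read-base string, `.` and `,` count toward the
#' reference base; letters count toward that nucleotide (case pooled);
#' `^` consumes the following mapping-quality character; `$` is skipped;
#' `+k`/`-k` followed by k bases (indels) are skipped; `*`, `>`, `<` and
#' `N` are ignored. Totals are taken from the parsed bases, not the depth
#' column; a disagreement with the depth column produces a warning.
#'
#' @param path file path (or connection) to a pileup.
#' @return data.frame with columns chrom, pos, ref, A, C, G, T.
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (li in seq_along(lines)) {
    fields <- strsplit(lines[li], "[ \t]+")[[1]]
    if (length(fields) < 5L) {
      stop_input("pileup parse error at line %d: expected at least 5 fields, got %d",
                 li, length(fields))
    }
    pos <- suppressWarnings(as.integer(fields[2]))
    ref <- toupper(fields[3])
    depth <- suppressWarnings(as.integer(fields[4]))
    if (is.na(pos) || pos < 1 || is.na(depth) || !(ref %in% BASES)) {
      stop_input("pileup parse error at line %d: bad position, depth or reference base",
                 li)
    }
    counts <- parse_pileup_bases(fields[5], ref, li)
    if (sum(counts) != depth) {
      warn_vbsnv("pileup line %d: depth field %d disagrees with %d parsed bases; using parsed counts",
                 li, depth, sum(counts))
    }
    out[[li]] <- data.frame(chrom = fields[1], pos = pos, ref = ref,
                            A = counts[1], C = counts[2], G = counts[3],
                            T = counts[4])
  }
  if (length(out) == 0) {
    return(empty_depth_chart())
  }
  do.call(rbind, out)
}

parse_pileup_bases <- function(s, ref, line_no) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  chars <- strsplit(s, "")[[1]]
  i <- 1L
  nc <- length(chars)
  while (i <= nc) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L  # skip the mapping-quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= nc && chars[j] %in% as.character(0:9)) j <- j + 1L
      if (j == i + 1L) {
        stop_input("pileup parse error at line %d: '%s' not followed by an indel length",
                   line_no, ch)
      }
      k <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + k  # skip the inserted/deleted bases
    } else if (ch == "." || ch == ",") {
      counts[ref] <- counts[ref] + 1L
      i <- i + 1L
    } else if (toupper(ch) %in% BASES) {
      counts[toupper(ch)] <- counts[toupper(ch)] + 1L
      i <- i + 1L
    } else if (ch %in% c("*", ">", "<", "N", "n")) {
      i <- i + 1L
    } else {
      stop_input("pileup parse error at line %d: unexpected character '%s' in read bases",
                 line_no, ch)
    }
  }
  counts
}

empty_depth_chart <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             A = integer(0), C = integer(0), G = integer(0), T = integer(0))
}

validate_depth_chart <- function(records) {
  if (!all(DEPTH_CHART_COLS %in% names(records))) {
    stop_input("depth chart must have columns: %s",
               paste(DEPTH_CHART_COLS, collapse = " "))
  }
  records
}

#' Read a depth-chart count table
#'
#' @param path tab-delimited file with header `chrom pos ref A C G T`.
#' @return data.frame of depth-chart records.
#' @export
read_depth_chart <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (!identical(names(raw), DEPTH_CHART_COLS)) {
    stop_input("depth chart %s: expected header '%s', got '%s'",
               path, paste(DEPTH_CHART_COLS, collapse = "\t"),
               paste(names(raw), collapse = "\t"))
  }
  if (nrow(raw) == 0) return(empty_depth_chart())
  pos <- suppressWarnings(as.integer(raw$pos))
  cnt <- lapply(BASES, function(b) suppressWarnings(as.numeric(raw[[b]])))
  names(cnt) <- BASES
  for (li in seq_len(nrow(raw))) {
    vals <- c(pos[li], vapply(cnt, `[`, numeric(1), li))
    if (any(is.na(vals)) || any(vals[-1] < 0) ||
        any(vals != round(vals)) || pos[li] < 1 ||
        !(raw$ref[li] %in% BASES)) {
      stop_input("depth chart %s: parse error at line %d", path, li + 1L)
    }
  }
  data.frame(chrom = raw$chrom, pos = pos, ref = raw$ref,
             A = as.integer(cnt$A), C = as.integer(cnt$C),
             G = as.integer(cnt$G), T = as.integer(cnt$T))
}

#' Write a depth-chart count table
#'
#' @param records data.frame of depth-chart records.
#' @param path output file path.
#' @export
write_depth_chart <- function(records, path) {
  validate_depth_chart(records)
  utils::write.table(records[, DEPTH_CHART_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a read-count matrix from per-replicate depth charts
#'
#' Positions are unioned across replicates and sorted; a position missing
#' from a replicate contributes zero depth there. All replicates must
#' agree on the chromosome and on the reference base at shared positions.
#'
#' @param replicate_records list of depth-chart data.frames, one per
#'   replicate.
#' @return A [read_count_matrix()].
#' @export
assemble_count_matrix <- function(replicate_records) {
  if (length(replicate_records) == 0) stop_input("no replicates given")
  replicate_records <- lapply(replicate_records, validate_depth_chart)
  chroms <- unique(unlist(lapply(replicate_records,
                                 function(x) unique(x$chrom))))
  if (length(chroms) > 1L) {
    stop_input("replicates span multiple chromosomes (%s); restrict to one region",
               paste(chroms, collapse = ","))
  }
  all_pos <- sort(unique(unlist(lapply(replicate_records, `[[`, "pos"))))
  J <- length(all_pos)
  N <- length(replicate_records)
  if (J == 0) stop_input("no positions in any replicate")

  ref <- rep(NA_character_, J)
  bc <- array(0L, dim = c(J, N, 4), dimnames = list(NULL, NULL, BASES))
  for (i in seq_len(N)) {
    rec <- replicate_records[[i]]
    idx <- match(rec$pos, all_pos)
    clash <- !is.na(ref[idx]) & ref[idx] != rec$ref
    if (any(clash)) {
      stop_input("conflicting reference base at position %s",
                 paste(all_pos[idx[clash]][1], collapse = ","))
    }
    ref[idx] <- rec$ref
    for (b in seq_along(BASES)) bc[idx, i, b] <- rec[[BASES[b]]]
  }
  # positions absent from every replicate cannot occur; absent ref means
  # the position appeared with zero counts only in some replicates
  read_count_matrix(bc, all_pos, ref, chroms)
}

depth_chart_from_matrix <- function(counts, replicate) {
  data.frame(chrom = counts$chrom, pos = counts$positions, ref = counts$ref,
             A = counts$base_counts[, replicate, 1],
             C = counts$base_counts[, replicate, 2],
             G = counts$base_counts[, replicate, 3],
             T = counts$base_counts[, replicate, 4])
}

#' Write variant calls as VCF 4.2
#'
#' Emits one record per called variant. ALT is the most frequent
#' non-reference base in the case sample's pooled counts (ties broken in
#' A < C < G < T order). INFO carries NRAF_CASE, NRAF_CTRL, DIFFPROB and
#' CHI2P. With `emit_filtered = TRUE`, provisional positions that failed
#' the chi-squared promotion are included with `FILTER=chi2_uniform`.
#'
#' @param calls data.frame from [call_variants()].
#' @param case_counts the case [read_count_matrix()].
#' @param path output path.
#' @param emit_filtered also emit provisional-but-uncalled records.
#' @param sample_name name recorded in the header.
#' @export
write_vcf <- function(calls, case_counts, path, emit_filtered = FALSE,
                      sample_name = "case") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=vbsnv %s",
            as.character(utils::packageVersion("vbsnv"))),
    sprintf("##vbsnv_sample=%s", sample_name),
    "##INFO=<ID=NRAF_CASE,Number=1,Type=Float,Description=\"Posterior mean NRAF in the case sample\">",
    "##INFO=<ID=NRAF_CTRL,Number=1,Type=Float,Description=\"Posterior mean NRAF in the control sample\">",
    "##INFO=<ID=DIFFPROB,Number=1,Type=Float,Description=\"Posterior probability of a case-control NRAF difference\">",
    "##INFO=<ID=CHI2P,Number=1,Type=Float,Description=\"Chi-squared p-value of the non-uniform base distribution test\">",
    "##FILTER=<ID=chi2_uniform,Description=\"Provisional variant with uniform non-reference base distribution\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
  keep <- if (emit_filtered) calls$provisional else calls$called
  rows <- character(0)
  if (any(keep)) {
    pooled <- apply(case_counts$base_counts, c(1, 3), sum)
    pos_idx <- match(calls$position, case_counts$positions)
    for (k in which(keep)) {
      j <- pos_idx[k]
      ref <- calls$ref[k]
      alt_bases <- setdiff(BASES, ref)
      alt_counts <- pooled[j, alt_bases]
      alt <- alt_bases[which.max(alt_counts)]  # ties: first in A<C<G<T
      info <- sprintf("NRAF_CASE=%.6g;NRAF_CTRL=%.6g;DIFFPROB=%.6g;CHI2P=%s",
                      calls$nraf_case[k], calls$nraf_control[k],
                      calls$diff_prob[k],
                      ifelse(is.na(calls$chi2_p[k]), ".",
                             sprintf("%.6g", calls$chi2_p[k])))
      filt <- if (calls$called[k]) "PASS" else "chi2_uniform"
      rows <- c(rows, paste(case_counts$chrom, calls$position[k], ".",
                            ref, alt, ".", filt, info, sep = "\t"))
    }
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Serialize / restore a fitted model estimate
#'
#' Writes a versioned JSON container with the model parameters,
#' variational parameters, ELBO trace and coordinates, at full numeric
#' precision, so that fits can be stored and the test step re-run without
#' refitting.
#'
#' @param est a `model_estimate`.
#' @param path output path.
#' @export
write_estimate <- function(est, path) {
  stopifnot(inherits(est, "model_estimate"))
  obj <- list(format = "vbsnv_estimate", version = 1L,
              chrom = est$chrom, positions = est$positions, ref = est$ref,
              mu0 = est$params$mu0, M0 = est$params$M0, M = est$params$M,
              gamma = est$vparams$gamma, delta = est$vparams$delta,
              elbo_trace = est$elbo_trace, converged = est$converged)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_estimate
#' @param path path to a file written by [write_estimate()].
#' @export
read_estimate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "vbsnv_estimate")) {
    stop_input("%s is not a vbsnv estimate file", path)
  }
  J <- length(obj$positions)
  delta <- obj$delta
  if (is.null(dim(delta)) || length(dim(delta)) != 3L) {
    delta <- array(unlist(delta), dim = c(J, length(unlist(delta)) / (2 * J), 2))
  }
  model_estimate(model_params(obj$mu0, obj$M0, obj$M),
                 variational_params(matrix(unlist(obj$gamma), ncol = 2),
                                    delta),
                 elbo_trace = obj$elbo_trace,
                 converged = obj$converged,
                 chrom = obj$chrom,
                 positions = as.integer(obj$positions),
                 ref = obj$ref)
}
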