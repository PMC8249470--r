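## The ping-pong 5' overlap signature.
##
## Offset convention: for a sense/antisense pair with 5' ends at plus-strand
## coordinates i (sense) and j (antisense), the offset is the overlap length
## o = j - i + 1; o = 10 is the ping-pong configuration (5' ends
## complementary across 10 nt).  Offsets 1..29 are tabulated.

PP_OFFSETS <- 1:29

#' 5' overlap offset between two alignments
#'
#' @param target,partner single TE alignments: lists or one-row data.frames
#'   with `family`, `strand`, `five_prime`.
#' @return the offset `o = j - i + 1` (overlap of the 5' ends) when the two
#'   alignments are on opposite strands and `o` is in 1..29; `NA` otherwise.
#'   Different families are a contract violation (error).
#' @export
#' @examples
#' a <- list(family = "TE1", strand = "sense", five_prime = 0)
#' b <- list(family = "TE1", strand = "antisense", five_prime = 9)
#' pair_offset(a, b)  # 10, the canonical ping-pong pair
pair_offset <- function(target, partner) {
  if (target$family != partner$family)
    stop("pair_offset called across families", call. = FALSE)
  if (target$strand == partner$strand) return(NA_integer_)
  i <- if (target$strand == "sense") target$five_prime else partner$five_prime
  j <- if (target$strand == "antisense") target$five_prime else
    partner$five_prime
  o <- as.integer(j - i + 1L)
  if (o >= 1L && o <= 29L) o else NA_integer_
}

#' Partner offset histogram of a single target alignment
#'
#' For every opposite-strand alignment in the same family with a valid
#' offset, the partner's cloning/sequencing count is added at that offset;
#' the histogram is normalized to 100% over offsets 1..29.
#'
#' @param target a single TE alignment (list or one-row data.frame).
#' @param family_alignments alignments of the same family (data.frame as
#'   returned by [map_library_to_panel()]).
#' @return named numeric vector over offsets 1..29 summing to 100, or an
#'   all-`NA` vector when the target has no partner.
#' @export
per_target_histogram <- function(target, family_alignments) {
  fa <- family_alignments[family_alignments$family == target$family, ,
                          drop = FALSE]
  opp <- fa[fa$strand != target$strand, , drop = FALSE]
  h <- setNames(numeric(29), PP_OFFSETS)
  if (nrow(opp)) {
    o <- if (target$strand == "sense")
      opp$five_prime - target$five_prime + 1L
    else
      target$five_prime - opp$five_prime + 1L
    ok <- o >= 1L & o <= 29L
    if (any(ok)) {
      mass <- rowsum(as.numeric(opp$count[ok]), o[ok])
      h[rownames(mass)] <- mass[, 1]
      return(100 * h / sum(h))
    }
  }
  h[] <- NA_real_
  h
}

## aggregate alignments to (family, strand, five_prime) position mass
aggregate_positions <- function(alignments) {
  key <- paste(alignments$family, alignments$strand, alignments$five_prime,
               sep = "\r")
  mass <- rowsum(as.numeric(alignments$count), key)
  nrows <- rowsum(rep(1L, nrow(alignments)), key)
  parts <- do.call(rbind, strsplit(rownames(mass), "\r", fixed = TRUE))
  data.frame(family = parts[, 1], strand = parts[, 2],
             five_prime = as.integer(parts[, 3]),
             mass = mass[, 1], nrows = nrows[, 1],
             stringsAsFactors = FALSE)
}

#' Combined count-weighted ping-pong histogram
#'
#' Every alignment (both strands, every placement) is a candidate target.
#' Each partnered target's normalized histogram contributes with weight
#' proportional to its cloning/sequencing count; targets without any valid
#' partner are excluded from both numerator and denominator.  The ping-pong
#' fraction is the combined value at offset 10.
#'
#' @param alignments TE alignments (data.frame from
#'   [map_library_to_panel()]); for `scope != "all"` only that family.
#' @param scope `"all"` (default) or a family id.
#' @return object of class `pingpong_histogram`: list with `scope`, `values`
#'   (named percent vector over offsets 1..29, all `NA` when no target has a
#'   partner), `n_targets`, `total_target_count`, `pingpong_fraction`.
#' @export
combined_histogram <- function(alignments, scope = "all") {
  if (scope != "all")
    alignments <- alignments[alignments$family == scope, , drop = FALSE]
  values <- setNames(rep(NA_real_, 29), PP_OFFSETS)
  n_targets <- 0L
  total_mass <- 0
  if (nrow(alignments)) {
    pos <- aggregate_positions(alignments)
    numer <- numeric(29)
    denom <- 0
    for (f in unique(pos$family)) {
      p <- pos[pos$family == f, , drop = FALSE]
      sp <- p[p$strand == "sense", , drop = FALSE]
      ap <- p[p$strand == "antisense", , drop = FALSE]
      contribute <- function(tp, op, sense_target) {
        ## tp: target positions; op: opposite-strand positions
        if (nrow(tp) == 0L || nrow(op) == 0L) return()
        shift <- if (sense_target) 0:28 else -(0:28)
        pm <- outer(tp$five_prime, shift, `+`)     # partner coordinate at o
        idx <- match(pm, op$five_prime)
        m <- matrix(ifelse(is.na(idx), 0, op$mass[idx]), nrow = nrow(tp))
        tot <- rowSums(m)
        part <- tot > 0
        if (!any(part)) return()
        h <- 100 * m[part, , drop = FALSE] / tot[part]
        w <- tp$mass[part]
        numer <<- numer + colSums(h * w)
        denom <<- denom + sum(w)
        n_targets <<- n_targets + sum(tp$nrows[part])
        total_mass <<- total_mass + sum(w)
      }
      contribute(sp, ap, sense_target = TRUE)
      contribute(ap, sp, sense_target = FALSE)
    }
    if (denom > 0) values[] <- numer / denom
  }
  structure(list(scope = scope, values = values, n_targets = n_targets,
                 total_target_count = total_mass,
                 pingpong_fraction = unname(values["10"])),
            class = "pingpong_histogram")
}

#' @export
print.pingpong_histogram <- function(x, ...) {
  cat(sprintf(paste0("Ping-pong histogram [%s]: %d partnered targets ",
                     "(count mass %.0f)\n"),
              x$scope, x$n_targets, x$total_target_count))
  if (all(is.na(x$values))) {
    cat("  undefined: no target has a partner\n")
  } else {
    cat(sprintf("  ping-pong fraction (offset 10): %.2f%%\n",
                x$pingpong_fraction))
    top <- sort(x$values, decreasing = TRUE)[1:3]
    cat("  top offsets:",
        paste(sprintf("%s=%.1f%%", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ping-pong fraction per TE family
#'
#' @param alignments TE alignments (data.frame).
#' @param families families to report (default all in `alignments`).
#' @return named numeric vector of percent values at offset 10; `NA` for
#'   families without partnered targets.
#' @export
pingpong_fraction_by_family <- function(alignments,
                                        families =
                                          sort(unique(alignments$family))) {
  vapply(families, function(f) {
    combined_histogram(alignments, scope = f)$pingpong_fraction
  }, numeric(1))
}

#' Export a ping-pong histogram as TSV
#'
#' Long format `scope offset percent` (29 rows per scope).
#'
#' @param histograms a `pingpong_histogram` or list of them.
#' @param path output path.
#' @export
write_pingpong_tsv <- function(histograms, path) {
  if (inherits(histograms, "pingpong_histogram"))
    histograms <- list(histograms)
  rows <- do.call(rbind, lapply(histograms, function(h)
    data.frame(scope = h$scope, offset = PP_OFFSETS,
               percent = unname(h$values))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
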