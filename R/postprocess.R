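# union-find over integer ids
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so labels
# that touch diagonally are merged afterwards.
label_matrix8 <- function(m) {
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # NW-SE diagonal pairs
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # NE-SW diagonal pairs
  pick <- function(a, b) {
    k <- a > 0L & b > 0L & a != b
    cbind(a[k], b[k])
  }
  pairs <- rbind(pick(a1, b1), pick(a2, b2))
  if (nrow(pairs)) {
    parent <- uf_new(nlab)
    for (r in seq_len(nrow(pairs))) {
      ra <- uf_find(parent, pairs[r, 1]); rb <- uf_find(parent, pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), function(i) uf_find(parent, i), integer(1))
    dense <- match(root, sort(unique(root)))
    lab[lab > 0L] <- dense[lab[lab > 0L]]
  }
  lab
}

# lexicographically smallest (row, col) foreground pixel, 1-based
mask_anchor <- function(m) {
  idx <- which(m > 0L)
  if (length(idx) == 0L) return(c(NA_integer_, NA_integer_))
  rows <- ((idx - 1L) %% nrow(m)) + 1L
  cols <- ((idx - 1L) %/% nrow(m)) + 1L
  o <- order(rows, cols)[1]
  c(rows[o], cols[o])
}

#' Label the 8-connected foreground regions of a mask
#'
#' Regions are returned sorted by area (descending), ties broken by the
#' lexicographically smallest foreground pixel `(row, col)` (ascending), so
#' the ordering is deterministic.
#'
#' @param mask a [mask_frame()] or binary matrix.
#' @return an object of class `labeled_regions`: a list of regions, each a
#'   list with `mask` (binary matrix), `area_px` and `anchor` (1-based
#'   `(row, col)` of the smallest foreground pixel). Empty input gives an
#'   empty list.
#' @export
label_regions <- function(mask) {
  m <- as_pixel_matrix(mask)
  lab <- label_matrix8(m)
  nlab <- max(lab)
  regs <- vector("list", nlab)
  for (k in seq_len(nlab)) {
    rk <- matrix(as.integer(lab == k), nrow(m), ncol(m))
    regs[[k]] <- list(mask = rk, area_px = sum(rk), anchor = mask_anchor(rk))
  }
  if (nlab > 1L) {
    areas <- vapply(regs, `[[`, numeric(1), "area_px")
    anchors <- t(vapply(regs, `[[`, integer(2), "anchor"))
    regs <- regs[order(-areas, anchors[, 1], anchors[, 2])]
  }
  structure(regs, class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %d region(s)%s\n", length(x),
              if (length(x)) sprintf(", areas: %s",
                paste(vapply(x, `[[`, numeric(1), "area_px"), collapse = ", "))
              else ""))
  invisible(x)
}

invalid_mask_frame <- function(dim, frame_index) {
  fr <- mask_frame(matrix(0L, dim[1], dim[2]), frame_index)
  attr(fr, "valid") <- FALSE
  fr
}

#' Largest-area rule for semantic segmentation output
#'
#' Resolves a multi-region semantic prediction by keeping the single largest
#' 8-connected component (ties broken by the smaller region anchor). An empty
#' input yields an empty mask flagged invalid (`attr(x, "valid") == FALSE`).
#' The known failure mode — the true nerve not being the largest region — is
#' not special-cased; the rule is applied as stated.
#'
#' @param mask a [mask_frame()] or binary matrix.
#' @return a [mask_frame()] with exactly one component (or empty + invalid).
#' @export
select_semantic_region <- function(mask) {
  m <- as_pixel_matrix(mask)
  fi <- frame_index_of(mask)
  regs <- label_regions(m)
  if (length(regs) == 0L) return(invalid_mask_frame(dim(m), fi))
  mask_frame(regs[[1]]$mask, fi)
}

#' Highest-confidence-candidate rule for instance segmentation output
#'
#' Picks the candidate with the maximal confidence score (ties: larger total
#' area, then smaller anchor), then returns the largest 8-connected block
#' within that candidate's mask. An empty candidate list yields an empty mask
#' flagged invalid.
#'
#' @param cands a [candidate_set()].
#' @return a [mask_frame()] with exactly one component (or empty + invalid).
#' @export
select_instance_candidate <- function(cands) {
  stopifnot(inherits(cands, "candidate_set"))
  if (length(cands$masks) == 0L)
    return(invalid_mask_frame(cands$dim, cands$frame_index))
  areas <- vapply(cands$masks, sum, numeric(1))
  anchors <- t(vapply(cands$masks, mask_anchor, integer(2)))
  anchors[is.na(anchors)] <- .Machine$integer.max  # empty candidate masks last
  o <- order(-cands$scores, -areas, anchors[, 1], anchors[, 2])[1]
  win <- cands$masks[[o]]
  if (sum(win) == 0L) return(invalid_mask_frame(cands$dim, cands$frame_index))
  select_semantic_region(mask_frame(win, cands$frame_index))
}

#' Post-process every frame of a sequence to a single-region mask
#'
#' @param seq a [mask_sequence()] (for instance mode it supplies the metadata
#'   and frame ordering; its pixel content is ignored when `method =
#'   "instance"`).
#' @param method `"semantic"` (largest-area rule), `"instance"`
#'   (highest-confidence candidate; requires `candidates`) or `"none"`
#'   (identity).
#' @param candidates list of [candidate_set()] objects matched by
#'   `frame_index` (instance mode).
#' @return a [mask_sequence()] whose frames each hold at most one component;
#'   frames with no usable prediction are empty and flagged invalid.
#' @export
postprocess_sequence <- function(seq, method = c("semantic", "instance", "none"),
                                 candidates = NULL) {
  stopifnot(inherits(seq, "mask_sequence"))
  method <- match.arg(method)
  if (method == "none") return(seq)
  frames <- if (method == "semantic") {
    lapply(seq$frames, select_semantic_region)
  } else {
    if (is.null(candidates)) stopf("instance post-processing needs candidates")
    ci <- vapply(candidates, `[[`, integer(1), "frame_index")
    lapply(seq$frames, function(fr) {
      j <- match(frame_index_of(fr), ci)
      if (is.na(j)) stopf("no candidate set for frame_index %d", frame_index_of(fr))
      select_instance_candidate(candidates[[j]])
    })
  }
  mask_sequence(frames, seq$meta)
}
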