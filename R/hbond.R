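# Geometric hydrogen-bond counting (Chandler criterion): a donor-acceptor
# pair is bonded when the Od-Oa distance stays below 0.35 nm and the
# H-Od-Oa angle does not exceed 35 degrees. Distances use the minimum-image
# convention in the periodic cubic box. Boundary semantics follow the
# criterion's wording: distance strictly <, angle inclusive <=.

#' Hydrogen-bond criterion
#'
#' @param oo_cutoff donor-acceptor oxygen distance cutoff, nm (strict `<`).
#' @param angle_cutoff H-Od-Oa angle cutoff, degrees (inclusive `<=`).
#' @return object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(oo_cutoff = 0.35, angle_cutoff = 35) {
  if (oo_cutoff <= 0 || angle_cutoff <= 0) stop("cutoffs must be positive")
  structure(list(oo_cutoff = oo_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criterion")
}

#' Donor/acceptor site frame
#'
#' Holds donor oxygen + hydrogen positions and acceptor oxygen positions
#' (nm) in a periodic cubic box, with species tags per site. CO2, which has
#' no O-H bond, enters only through acceptor sites.
#'
#' @param box_side cubic box edge, nm.
#' @param donor_o,donor_h matrices (n_donors x 3) of Od and H positions.
#' @param acceptor_o matrix (n_acceptors x 3) of Oa positions.
#' @param donor_species,acceptor_species character tags per site.
#' @return object of class `donor_acceptor_frame`.
#' @export
donor_acceptor_frame <- function(box_side, donor_o, donor_h, acceptor_o,
                                 donor_species = NULL,
                                 acceptor_species = NULL) {
  donor_o <- as.matrix(donor_o); donor_h <- as.matrix(donor_h)
  acceptor_o <- as.matrix(acceptor_o)
  if (box_side <= 0) stop("box_side must be positive")
  if (nrow(donor_o) != nrow(donor_h))
    stop("each donor oxygen needs exactly one hydrogen")
  oh <- min_image(donor_h - donor_o, box_side)
  if (nrow(donor_o) > 0 && any(sqrt(rowSums(oh^2)) >= 0.15))
    stop("donor hydrogen detached from its oxygen (O-H >= 0.15 nm)")
  structure(list(
    box_side = box_side, donor_o = donor_o, donor_h = donor_h,
    acceptor_o = acceptor_o,
    donor_species = donor_species %||% rep("", nrow(donor_o)),
    acceptor_species = acceptor_species %||% rep("", nrow(acceptor_o))),
    class = "donor_acceptor_frame")
}

# minimum-image displacement components for a cubic box
min_image <- function(d, box_side) d - box_side * round(d / box_side)

#' Count hydrogen bonds in a donor/acceptor frame
#'
#' A donor may bond several acceptors; coincident donor/acceptor oxygen
#' sites (the same physical atom listed in both roles) are skipped. The
#' cell-list path is used when the box exceeds three cutoffs per side and
#' both site lists are non-trivial; the all-pairs path is the tested
#' fallback and oracle.
#'
#' @param frame a [donor_acceptor_frame()].
#' @param criterion a [hbond_criterion()].
#' @param method `"auto"`, `"cell"` or `"brute"`.
#' @return list with `count` (integer) and `pairs` (data.frame: donor,
#'   acceptor, distance_nm, angle_deg, donor_species, acceptor_species).
#' @export
count_hbonds <- function(frame, criterion = hbond_criterion(),
                         method = c("auto", "cell", "brute")) {
  method <- match.arg(method)
  nd <- nrow(frame$donor_o); na <- nrow(frame$acceptor_o)
  if (nd == 0 || na == 0)
    return(list(count = 0L, pairs = empty_pairs()))
  L <- frame$box_side
  if (method == "auto")
    method <- if (L > 3 * criterion$oo_cutoff && nd * na > 400) "cell"
              else "brute"
  if (method == "cell" && floor(L / criterion$oo_cutoff) < 3)
    method <- "brute"
  cand <- if (method == "brute") {
    cbind(rep(seq_len(nd), each = na), rep(seq_len(na), nd))
  } else {
    cell_candidates(frame$donor_o, frame$acceptor_o, L, criterion$oo_cutoff)
  }
  if (nrow(cand) == 0) return(list(count = 0L, pairs = empty_pairs()))
  di <- cand[, 1]; ai <- cand[, 2]
  doa <- min_image(frame$acceptor_o[ai, , drop = FALSE] -
                     frame$donor_o[di, , drop = FALSE], L)
  dist <- sqrt(rowSums(doa^2))
  keep <- dist < criterion$oo_cutoff & dist > 1e-9
  if (!any(keep)) return(list(count = 0L, pairs = empty_pairs()))
  di <- di[keep]; ai <- ai[keep]; doa <- doa[keep, , drop = FALSE]
  dist <- dist[keep]
  oh <- min_image(frame$donor_h[di, , drop = FALSE] -
                    frame$donor_o[di, , drop = FALSE], L)
  cosang <- rowSums(oh * doa) / (sqrt(rowSums(oh^2)) * dist)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  keep <- ang <= criterion$angle_cutoff
  pairs <- data.frame(donor = di[keep], acceptor = ai[keep],
                      distance_nm = dist[keep], angle_deg = ang[keep],
                      donor_species = frame$donor_species[di[keep]],
                      acceptor_species = frame$acceptor_species[ai[keep]])
  pairs <- pairs[order(pairs$donor, pairs$acceptor), , drop = FALSE]
  rownames(pairs) <- NULL
  list(count = nrow(pairs), pairs = pairs)
}

empty_pairs <- function() {
  data.frame(donor = integer(), acceptor = integer(),
             distance_nm = numeric(), angle_deg = numeric(),
             donor_species = character(), acceptor_species = character())
}

# candidate donor-acceptor index pairs from a periodic cell grid
cell_candidates <- function(donor_o, acceptor_o, L, cutoff) {
  ncell <- floor(L / cutoff)
  w <- L / ncell
  aidx <- (floor((acceptor_o %% L) / w)) %% ncell # n_a x 3 integer cells
  akey <- aidx[, 1] + ncell * (aidx[, 2] + ncell * aidx[, 3])
  bucket <- split(seq_len(nrow(acceptor_o)), akey)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_d <- integer(0); out_a <- integer(0)
  didx <- (floor((donor_o %% L) / w)) %% ncell
  for (i in seq_len(nrow(donor_o))) {
    cells <- t((t(offs) + didx[i, ]) %% ncell)
    keys <- as.character(cells[, 1] + ncell * (cells[, 2] + ncell * cells[, 3]))
    cand <- unlist(bucket[keys], use.names = FALSE)
    if (length(cand)) {
      out_d <- c(out_d, rep.int(i, length(cand)))
      out_a <- c(out_a, cand)
    }
  }
  cbind(out_d, out_a)
}

#' Time-averaged per-species hydrogen-bond count ratio
#'
#' Counts, per frame, the bonds in which each species participates (as
#' donor or acceptor) and returns the ratio of the time-averaged counts
#' a : b. A denominator species with no bonds in any frame yields NaN with
#' a warning (undefined ratio).
#'
#' @param frame_series list of [donor_acceptor_frame()] objects.
#' @param species_a,species_b species tags.
#' @param criterion a [hbond_criterion()].
#' @param method passed to [count_hbonds()].
#' @return the ratio mean(count_a) / mean(count_b).
#' @export
hbond_ratio <- function(frame_series, species_a, species_b,
                        criterion = hbond_criterion(),
                        method = c("auto", "cell", "brute")) {
  method <- match.arg(method)
  counts <- vapply(frame_series, function(fr) {
    p <- count_hbonds(fr, criterion, method)$pairs
    inv_a <- p$donor_species == species_a | p$acceptor_species == species_a
    inv_b <- p$donor_species == species_b | p$acceptor_species == species_b
    c(sum(inv_a), sum(inv_b))
  }, numeric(2))
  if (sum(counts[2, ]) == 0) {
    warning("species '", species_b,
            "' forms no hydrogen bonds in any frame: ratio undefined")
    return(NaN)
  }
  mean(counts[1, ]) / mean(counts[2, ])
}
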