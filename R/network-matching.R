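# Template matching: correlate group maps with binary reference-network
# templates, classify components as uniquely detected networks, and select
# the ICA model order that detects the most networks.

#' Correlate group component maps with reference templates
#'
#' Pearson correlation of each component's group Z map with each binary
#' template, computed over brain-mask voxels only.
#'
#' @param gmap a `group_fc_map`, or a d x V matrix of map values on the
#'   brain-mask voxels.
#' @param templates list of binary 3D arrays (or length-V vectors already on
#'   mask voxels).
#' @param brain_mask 3D binary array defining the correlation domain.
#' @return d x R matrix of correlations; column names from template names.
#' @export
correlate_with_templates <- function(gmap, templates, brain_mask) {
  idx <- which(brain_mask != 0)
  if (inherits(gmap, "group_fc_map")) {
    if (!is.null(gmap$voxels) && !identical(gmap$voxels, idx)) {
      # map defined on its own voxel set; restrict to brain-mask voxels
      keep <- match(idx, gmap$voxels)
      if (anyNA(keep))
        stopf("group map does not cover all brain-mask voxels")
      vals <- gmap$z[, keep, drop = FALSE]
    } else vals <- gmap$z
  } else vals <- as.matrix(gmap)
  tv <- vapply(templates, function(tm)
    if (length(dim(tm)) == 3L) as.numeric(tm[idx]) else as.numeric(tm),
    numeric(length(idx)))
  if (any(apply(tv, 2L, stats::sd) == 0))
    stopf("a template is constant inside the brain mask")
  r <- matrix(NA_real_, nrow(vals), ncol(tv))
  for (k in seq_len(nrow(vals))) {
    if (stats::sd(vals[k, ]) == 0) stopf("degenerate map: component %d is constant", k)
    r[k, ] <- stats::cor(vals[k, ], tv)
  }
  dimnames(r) <- list(paste0("IC", seq_len(nrow(vals))),
                      if (!is.null(names(templates))) names(templates)
                      else paste0("network", seq_len(ncol(tv))))
  r
}

#' Assign components to networks (unique / ambiguous / unmatched)
#'
#' A component is the UNIQUE detector of network n iff its correlation with
#' n reaches the threshold, its correlation with every other network stays
#' below it, and no other such candidate has a higher correlation with n.
#' Candidates tied at a network's best correlation are all AMBIGUOUS;
#' everything else is UNMATCHED. The assignment is injective.
#'
#' @param r d x R correlation matrix from [correlate_with_templates()].
#' @param r_star detection threshold (default 0.4).
#' @return data.frame: `component`, `network` (NA unless unique), `r`
#'   (matched correlation, NA unless unique), `status`.
#' @export
assign_networks <- function(r, r_star = 0.4) {
  r <- as.matrix(r)
  d <- nrow(r); nn <- ncol(r)
  status <- rep("unmatched", d)
  network <- rep(NA_integer_, d)
  matched_r <- rep(NA_real_, d)
  # single-network candidates: exactly one column at/above threshold
  above <- r >= r_star
  cand_net <- ifelse(rowSums(above) == 1L, apply(above, 1L, which.max), NA)
  for (n in seq_len(nn)) {
    claimants <- which(!is.na(cand_net) & cand_net == n)
    if (length(claimants) == 0L) next
    best <- max(r[claimants, n])
    winners <- claimants[r[claimants, n] == best]
    if (length(winners) >= 2L) {
      status[winners] <- "ambiguous"
    } else {
      status[winners] <- "unique"
      network[winners] <- n
      matched_r[winners] <- best
    }
  }
  data.frame(component = seq_len(d),
             network = if (!is.null(colnames(r))) colnames(r)[network]
             else network,
             network_index = network, r = matched_r, status = status,
             stringsAsFactors = FALSE)
}

#' Select the ICA model order from a dimension sweep
#'
#' Given per-dimension match tables, counts uniquely detected networks U(d)
#' and picks the smallest dimension achieving the maximum count; the full
#' sweep table (d, U(d), summed matched r) is always returned.
#'
#' @param sweep named list, one entry per dimension, each containing `r`
#'   (match matrix) and `assignment` (from [assign_networks()]); names are
#'   the dimensions.
#' @return list of class `dimension_selection`: `chosen_d` (NA when no
#'   network is detected anywhere), `assignment` at the chosen d, `status`
#'   ("ok" or "no network detected"), `sweep_table`.
#' @export
select_dimension <- function(sweep) {
  if (length(sweep) == 0L) stopf("empty dimension sweep")
  ds <- as.integer(names(sweep))
  if (anyNA(ds)) ds <- seq_along(sweep)
  tab <- data.frame(
    d = ds,
    n_unique = vapply(sweep, function(s)
      if (!is.null(s$error)) NA_integer_
      else sum(s$assignment$status == "unique"), integer(1)),
    sum_matched_r = vapply(sweep, function(s)
      if (!is.null(s$error)) NA_real_
      else sum(s$assignment$r, na.rm = TRUE), numeric(1)))
  tab <- tab[order(tab$d), ]
  rownames(tab) <- NULL
  if (all(is.na(tab$n_unique)) || max(tab$n_unique, na.rm = TRUE) == 0L)
    return(structure(list(chosen_d = NA_integer_, assignment = NULL,
                          status = "no network detected", sweep_table = tab),
                     class = "dimension_selection"))
  chosen <- tab$d[which.max(tab$n_unique)]   # first max = smallest d; NAs skipped
  structure(list(chosen_d = chosen,
                 assignment = sweep[[match(chosen, ds)]]$assignment,
                 status = "ok", sweep_table = tab),
            class = "dimension_selection")
}

#' @export
print.dimension_selection <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<dimension_selection> chosen d = %d (%d unique networks)\n",
                x$chosen_d, max(x$sweep_table$n_unique)))
  else cat("<dimension_selection> no network detected\n")
  print(x$sweep_table)
  invisible(x)
}
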