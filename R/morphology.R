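#' Build a stylized granule cell morphology
#'
#' Constructs the compartmental tree of a type I, II or III granule cell:
#' a soma, an ascending dendritic trunk, short deep-dendrite branches off
#' the proximal trunk, and a terminal field that branches with depth (2
#' branches at the base of the field, 3 in the middle, 4 at the tip). The
#' per-class compartment budgets reproduce the reference counts exactly
#' (112, 114 and 89 non-spine compartments for types I, II and III).
#' Construction is fully deterministic.
#'
#' @param cell_class One of `"I"`, `"II"`, `"III"`.
#' @param geometry_overrides Optional named list overriding entries of
#'   [cell_class_params()] (metric geometry only; counts are fixed).
#' @return A `granule_morphology` object: a list with a `compartments`
#'   data frame (id, parent_id, region, zone, branch, seg, length, diameter,
#'   extra_area, path_dist), an initially empty `spines` table, and the
#'   structural parameters used.
#' @export
build_cell <- function(cell_class, geometry_overrides = NULL) {
  if (length(cell_class) != 1 || !as.character(cell_class) %in% c("I", "II", "III"))
    stop("unknown cell class '", paste(cell_class, collapse = ","),
         "': must be one of \"I\", \"II\", \"III\"")
  p <- cell_class_params(cell_class)
  if (!is.null(geometry_overrides)) {
    bad <- setdiff(names(geometry_overrides), names(p))
    if (length(bad)) stop("unknown geometry override(s): ", paste(bad, collapse = ", "))
    fixed <- c("n_compartments", "n_spines", "n_experimental_spines")
    if (any(names(geometry_overrides) %in% fixed))
      stop("per-class counts are fixed and cannot be overridden")
    p[names(geometry_overrides)] <- geometry_overrides
  }

  rows <- list()
  add <- function(parent_id, region, zone, branch, seg, length, diameter) {
    id <- length(rows) + 1L
    rows[[id]] <<- data.frame(
      id = id, parent_id = if (is.null(parent_id)) NA_integer_ else parent_id,
      region = region, zone = zone, branch = branch, seg = seg,
      length = length, diameter = diameter, extra_area = 0,
      stringsAsFactors = FALSE)
    id
  }

  soma <- add(NULL, "soma", NA_character_, NA_integer_, 1L,
              p$soma_length, p$soma_diameter)

  # trunk: a single chain of p$trunk_n segments
  prev <- soma
  trunk_ids <- integer(p$trunk_n)
  for (s in seq_len(p$trunk_n)) {
    zone <- if (s <= p$trunk_proximal_n) "proximal" else "distal"
    prev <- add(prev, "trunk", zone, 1L, s, p$trunk_seg_length,
                p$trunk_diameter[[zone]])
    trunk_ids[s] <- prev
  }

  # deep dendrites: n_deep_branches chains off the proximal trunk
  for (b in seq_len(p$n_deep_branches)) {
    prev <- trunk_ids[1L]
    for (s in seq_len(p$deep_seg_n))
      prev <- add(prev, "deep", NA_character_, b, s,
                  p$deep_seg_length, p$deep_diameter)
  }

  # terminal field: base (2 branches) -> middle (3) -> tip (4).
  # Branch b1 of the base splits into middle m1, m2; b2 continues as m3.
  # m1 splits into tips t1, t2; m2 continues as t3; m3 as t4.
  zn <- p$terminal_zone_n
  grow <- function(parent_id, zone, branch) {
    prev <- parent_id
    for (s in seq_len(zn[[zone]]))
      prev <- add(prev, "terminal", zone, branch, s,
                  p$terminal_seg_length, p$terminal_diameter[[zone]])
    prev
  }
  trunk_end <- trunk_ids[p$trunk_n]
  b_end <- c(grow(trunk_end, "base", 1L), grow(trunk_end, "base", 2L))
  m_parent <- c(b_end[1], b_end[1], b_end[2])
  m_end <- vapply(1:3, function(b) grow(m_parent[b], "middle", b), integer(1))
  t_parent <- c(m_end[1], m_end[1], m_end[2], m_end[3])
  for (b in 1:4) grow(t_parent[b], "tip", b)

  comp <- do.call(rbind, rows)
  stopifnot(nrow(comp) == p$n_compartments)
  comp$path_dist <- .path_distances(comp)

  structure(list(cell_class = as.character(cell_class), compartments = comp,
                 spines = data.frame(neck_id = integer(0), head_id = integer(0),
                                     parent_id = integer(0)),
                 params = p),
            class = "granule_morphology")
}

# midpoint-to-midpoint path distance from the soma (um)
.path_distances <- function(comp) {
  d <- numeric(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    pid <- comp$parent_id[i]
    d[i] <- if (is.na(pid)) 0 else
      d[pid] + comp$length[pid] / 2 + comp$length[i] / 2
  }
  d
}

#' Attach dendritic spines to a morphology
#'
#' Places one two-compartment spine (neck + head) per eligible compartment,
#' in a deterministic order, until the class's spine budget is reached.
#' Types I and II bear spines on every compartment including the soma
#' (granule cell somata carry gemmules); type III excludes the soma, the
#' proximal trunk and the deep dendrites, and fills from the distal trunk
#' and the terminal tip downward. Spine dimensions are fixed: neck 0.23 um
#' diameter x 1.9 um length, head 0.8 um x 0.8 um.
#'
#' @param tree A `granule_morphology` from [build_cell()], without spines.
#' @param cell_class Class label; defaults to the tree's own class.
#' @return The tree with `spines` filled in and spine neck/head compartments
#'   appended to `compartments`.
#' @export
place_spines <- function(tree, cell_class = tree$cell_class) {
  stopifnot(inherits(tree, "granule_morphology"))
  if (nrow(tree$spines) > 0) stop("tree already has spines")
  if (!identical(as.character(cell_class), tree$cell_class))
    stop("cell_class does not match the tree")
  p <- tree$params
  comp <- tree$compartments
  hosts <- .spine_host_order(comp, p)
  if (length(hosts) < p$n_spines)
    stop("only ", length(hosts), " spine-eligible compartments for ",
         p$n_spines, " spines")
  hosts <- hosts[seq_len(p$n_spines)]

  n0 <- nrow(comp)
  nsp <- length(hosts)
  neck_ids <- n0 + 2L * seq_len(nsp) - 1L
  head_ids <- neck_ids + 1L
  spine_rows <- data.frame(
    id = as.integer(rbind(neck_ids, head_ids)),
    parent_id = as.integer(rbind(hosts, neck_ids)),
    region = rep(c("spine_neck", "spine_head"), nsp),
    zone = NA_character_, branch = NA_integer_, seg = 1L,
    length = rep(c(p$spine_neck_length, p$spine_head_length), nsp),
    diameter = rep(c(p$spine_neck_diameter, p$spine_head_diameter), nsp),
    extra_area = 0, path_dist = 0, stringsAsFactors = FALSE)
  comp <- rbind(comp, spine_rows)
  comp$path_dist <- .path_distances(comp)
  tree$compartments <- comp
  tree$spines <- data.frame(neck_id = neck_ids, head_id = head_ids,
                            parent_id = hosts)
  tree
}

# deterministic eligibility order for spine placement
.spine_host_order <- function(comp, p) {
  dend <- comp[comp$region %in% c("soma", "trunk", "deep", "terminal"), ]
  if (length(p$spine_exclusions) == 0) return(dend$id)
  keep <- !(dend$region == "soma" & "soma" %in% p$spine_exclusions) &
          !(dend$region == "deep" & "deep" %in% p$spine_exclusions) &
          !(dend$region == "trunk" & dend$zone == "proximal" &
              "proximal_trunk" %in% p$spine_exclusions)
  dend <- dend[keep, ]
  # distal trunk first (proximal to distal), then terminal zones tip ->
  # middle -> base, most distal segments first within a zone
  trunk <- dend[dend$region == "trunk", ]
  trunk <- trunk$id[order(trunk$seg)]
  term_order <- function(zone) {
    z <- dend[dend$region == "terminal" & dend$zone == zone, ]
    z$id[order(-z$seg, z$branch)]
  }
  c(trunk, term_order("tip"), term_order("middle"), term_order("base"))
}

#' Missing-spine membrane area correction
#'
#' The reference cells carry more pedunculated spines than the model has
#' compartments; the membrane area of the spines that are not explicitly
#' modeled (3.37 um^2 each) is added back as extra membrane area,
#' distributed uniformly over the spine-bearing compartments.
#'
#' @param tree A `granule_morphology` with spines placed.
#' @param cell_class Class label; defaults to the tree's class.
#' @param area_per_spine Membrane area per missing spine, um^2.
#' @return The tree with `extra_area` set on the spine-bearing compartments.
#' @export
apply_missing_spine_correction <- function(tree, cell_class = tree$cell_class,
                                           area_per_spine = 3.37) {
  stopifnot(inherits(tree, "granule_morphology"))
  if (nrow(tree$spines) == 0) stop("place spines before applying the correction")
  p <- tree$params
  missing <- p$n_experimental_spines - p$n_spines
  if (missing < 0) stop("negative missing-spine count")
  if (area_per_spine == 0 || missing == 0) return(tree)
  total <- missing * area_per_spine
  hosts <- tree$spines$parent_id
  tree$compartments$extra_area[hosts] <-
    tree$compartments$extra_area[hosts] + total / length(hosts)
  tree
}

#' Build, spine and correct a morphology in one call
#'
#' @param cell_class One of `"I"`, `"II"`, `"III"`.
#' @param geometry_overrides Passed to [build_cell()].
#' @return A complete `granule_morphology`.
#' @export
build_morphology <- function(cell_class, geometry_overrides = NULL) {
  apply_missing_spine_correction(
    place_spines(build_cell(cell_class, geometry_overrides)))
}

#' Select spines for stimulation
#'
#' Implements the stimulation geometries of the experiments: terminal and
#' deep selections pick one spine per sibling branch at the same path
#' distance from the soma (spines "in the same horizontal plane"); trunk
#' selections pick spines ordered by increasing path distance from the
#' soma. `terminal_tip` selects the most distal spine of each tip branch,
#' `terminal_middle`/`terminal_base` the mid-zone spine of each middle/base
#' branch, `deep` the most distal spine of each deep branch.
#'
#' @param tree A spined `granule_morphology`.
#' @param location One of `"terminal_tip"`, `"terminal_middle"`,
#'   `"terminal_base"`, `"trunk"`, `"deep"`.
#' @param n Number of spines to select.
#' @return Integer vector of `n` spine head compartment ids.
#' @export
select_spines <- function(tree, location, n) {
  stopifnot(inherits(tree, "granule_morphology"), n >= 1)
  location <- match.arg(location, c("terminal_tip", "terminal_middle",
                                    "terminal_base", "trunk", "deep"))
  comp <- tree$compartments
  sp <- tree$spines
  host <- comp[sp$parent_id, ]

  pick_plane <- function(region, zone, seg_pick) {
    in_reg <- host$region == region & (is.na(zone) | host$zone %in% zone)
    if (!any(in_reg))
      stop("type ", tree$cell_class, " granule neuron models have no spines ",
           "in the ", if (region == "deep") "deep dendrites" else region)
    hh <- host[in_reg, ]
    seg_use <- seg_pick(hh$seg)
    plane <- hh[hh$seg == seg_use, ]
    plane <- plane[order(plane$branch), ]
    if (n > nrow(plane))
      stop("at most ", nrow(plane), " spines available on distinct branches at ",
           location, " for type ", tree$cell_class)
    sp$head_id[match(plane$id[seq_len(n)], sp$parent_id)]
  }

  switch(location,
    terminal_tip    = pick_plane("terminal", "tip", max),
    terminal_middle = pick_plane("terminal", "middle", function(s) 2L),
    terminal_base   = pick_plane("terminal", "base", function(s) ceiling(max(s) / 2) + 2L),
    deep            = pick_plane("deep", NA, max),
    trunk = {
      on_trunk <- host$region == "trunk"
      if (!any(on_trunk)) stop("no spines on the trunk")
      hh <- host[on_trunk, ]
      hh <- hh[order(hh$path_dist), ]
      if (n > nrow(hh))
        stop("at most ", nrow(hh), " trunk spines available for type ",
             tree$cell_class)
      sp$head_id[match(hh$id[seq_len(n)], sp$parent_id)]
    })
}

#' Structural summary of a morphology
#'
#' @param tree A `granule_morphology`.
#' @return A list with the non-spine compartment count, spine count,
#'   per-region compartment and spine counts, and total membrane area
#'   (um^2, including spines and the missing-spine correction).
#' @export
summarize_morphology <- function(tree) {
  stopifnot(inherits(tree, "granule_morphology"))
  comp <- tree$compartments
  dend <- comp[!comp$region %in% c("spine_neck", "spine_head"), ]
  host_region <- if (nrow(tree$spines))
    table(comp$region[tree$spines$parent_id]) else table(character(0))
  list(
    cell_class = tree$cell_class,
    n_compartments = nrow(dend),
    n_spines = nrow(tree$spines),
    compartments_by_region = table(dend$region),
    spines_by_host_region = host_region,
    total_area_um2 = sum(pi * comp$diameter * comp$length) + sum(comp$extra_area)
  )
}

#' @export
summary.granule_morphology <- function(object, ...) summarize_morphology(object)

#' @export
print.granule_morphology <- function(x, ...) {
  s <- summarize_morphology(x)
  cat("Granule cell morphology, type ", x$cell_class, "\n",
      "  compartments: ", s$n_compartments,
      " (", paste(names(s$compartments_by_region),
                  as.integer(s$compartments_by_region),
                  sep = "=", collapse = ", "), ")\n",
      "  spines: ", s$n_spines, "\n",
      "  total membrane area: ", format(s$total_area_um2, digits = 6),
      " um^2\n", sep = "")
  invisible(x)
}

#' Check structural invariants of a morphology
#'
#' Verifies single-rootedness, acyclicity and connectedness of the
#' compartment tree, positive geometry, spine attachment rules (necks on
#' dendritic compartments, heads on necks, at most one spine per host) and
#' the per-class count budget.
#'
#' @param tree A `granule_morphology`.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_morphology <- function(tree) {
  comp <- tree$compartments
  if (sum(is.na(comp$parent_id)) != 1) stop("exactly one root required")
  if (any(comp$length <= 0) || any(comp$diameter <= 0))
    stop("non-positive geometry")
  # parents must precede children (construction order) => acyclic; check reach
  root <- comp$id[is.na(comp$parent_id)]
  if (comp$region[root] != "soma") stop("root must be the soma")
  ok <- !is.na(comp$parent_id) & comp$parent_id < comp$id
  if (any(!ok[-root])) stop("parent ids must precede children")
  for (i in seq_len(nrow(tree$spines))) {
    nk <- tree$spines$neck_id[i]; hd <- tree$spines$head_id[i]
    if (!comp$region[comp$parent_id[nk]] %in% c("soma", "trunk", "deep", "terminal"))
      stop("spine neck not attached to a dendritic compartment")
    if (comp$parent_id[hd] != nk) stop("spine head not attached to its neck")
  }
  if (anyDuplicated(tree$spines$parent_id))
    stop("more than one spine on a compartment")
  invisible(TRUE)
}
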