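# memoised models and shared simulation results so expensive runs are done
# once per test session
.cache <- new.env(parent = emptyenv())

get_model <- function(cls) {
  key <- paste0("model_", cls)
  if (is.null(.cache[[key]])) .cache[[key]] <- granule_model(cls)
  .cache[[key]]
}

get_min_spines <- function(cls, location, dt_ms = 0.01) {
  key <- paste0("ms_", cls, "_", location)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- min_spines_for_spike(get_model(cls), location,
                                          dt_ms = dt_ms)
  .cache[[key]]
}

# a minimal hand-built passive morphology for solver oracle tests
passive_tree <- function(parent_ids, lengths, diameters) {
  n <- length(parent_ids)
  comp <- data.frame(
    id = seq_len(n), parent_id = parent_ids,
    region = c("soma", rep("deep", n - 1)),
    zone = NA_character_, branch = 1L, seg = seq_len(n),
    length = lengths, diameter = diameters, extra_area = 0,
    stringsAsFactors = FALSE)
  comp$path_dist <- 0
  structure(list(cell_class = "synthetic", compartments = comp,
                 spines = data.frame(neck_id = integer(0),
                                     head_id = integer(0),
                                     parent_id = integer(0)),
                 params = NULL),
            class = "granule_morphology")
}

passive_biophys <- function(g_pas = 1, cm = 0.01, ra = 1) {
  bp <- default_biophysics("I")
  bp$passive$g_pas <- g_pas
  bp$passive$cm <- cm
  bp$passive$ra <- ra
  for (r in names(bp$densities)) bp$densities[[r]][] <- 0
  bp
}

# dense-matrix reference for one Crank-Nicolson step on a passive tree
dense_cn_step <- function(tree, bp, v_init_mV, dt_ms) {
  comp <- tree$compartments
  n <- nrow(comp)
  area <- (pi * comp$diameter * comp$length + comp$extra_area) * 1e-12
  cm <- bp$passive$cm * area
  gp <- bp$passive$g_pas * area
  half <- bp$passive$ra * (comp$length * 1e-6 / 2) /
    (pi * (comp$diameter * 1e-6 / 2)^2)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    p <- comp$parent_id[i]
    if (!is.na(p)) {
      g <- 1 / (half[i] + half[p])
      L[i, i] <- L[i, i] + g; L[p, p] <- L[p, p] + g
      L[i, p] <- L[i, p] - g; L[p, i] <- L[p, i] - g
    }
  }
  dt <- dt_ms / 1000
  v <- v_init_mV / 1000
  e <- rep(-65 / 1000, n)
  A <- diag(cm / dt + gp / 2) + L / 2
  b <- (diag(cm / dt - gp / 2) - L / 2) %*% v + gp * e
  as.numeric(solve(A, b)) * 1000
}

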