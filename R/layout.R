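#' Standard 64-channel scalp layout (plus earlobe references)
#'
#' Builds a standard extended 10-20 (10-10) montage of 64 scalp electrodes on
#' a unit sphere, plus the two earlobe reference channels `A1` and `A2`.
#' Positions are constructed geometrically from the 10-10 convention: the
#' nasion-inion and ear-to-ear arcs span 180 degrees, electrode rows sit at
#' 10% (18 degree) steps, and intermediate electrodes are spaced evenly
#' between the midline and the circumferential ring of their row. The montage
#' contains all electrodes used by the analysis defaults (PO4, FCz, Pz, Fz,
#' PO3, C5).
#'
#' @return A data frame with one row per channel and columns `name`, `x`,
#'   `y`, `z` (unit-sphere coordinates: +y nasion, +x right, +z vertex),
#'   `fx`, `fy` (flat 2D projection used for adjacency and display) and
#'   `type` (`"scalp"` or `"ref"`).
#' @export
#' @examples
#' lay <- standard_layout_64()
#' subset(lay, name %in% c("C5", "PO3", "Pz"))
standard_layout_64 <- function() {
  # rows: midline inclination (deg from vertex) and ring azimuth (deg from
  # front) where the row meets the circumferential ring
  flat <- list()
  add <- function(name, rho, ang_deg, side) {
    # rho: flat radius in units of the circumferential ring (incl 72 deg)
    # ang_deg: angle from the front midline, side: -1 left, +1 right, 0 mid
    flat[[length(flat) + 1L]] <<- data.frame(
      name = name, rho = rho, ang = ang_deg * side,
      stringsAsFactors = FALSE)
  }
  # midline, front to back
  mids <- data.frame(
    name = c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz", "Iz"),
    rho  = c(1, 0.75, 0.5, 0.25, 0, 0.25, 0.5, 0.75, 1, 1.25),
    ang  = c(0, 0, 0, 0, 0, 180, 180, 180, 180, 180))
  for (i in seq_len(nrow(mids))) add(mids$name[i], mids$rho[i], mids$ang[i], 1)

  # circumferential ring positions (angle from front midline, per side)
  ring <- c(Fp = 18, AF = 36, F = 54, FT = 72, T = 90, TP = 108,
            P = 126, PO = 144, O = 162)
  lateral_rows <- list(
    # row label, midline rho, ring label, ring electrode name stem,
    # intermediate names ordered from midline outwards
    list(mid_rho = 1,    ring = "Fp", outer = c("Fp1", "Fp2"), inner = NULL),
    list(mid_rho = 0.75, ring = "AF", outer = c("AF7", "AF8"),
         inner = list(c("AF3"), c("AF4"))),
    list(mid_rho = 0.5,  ring = "F",  outer = c("F7", "F8"),
         inner = list(c("F1", "F3", "F5"), c("F2", "F4", "F6"))),
    list(mid_rho = 0.25, ring = "FT", outer = c("FT7", "FT8"),
         inner = list(c("FC1", "FC3", "FC5"), c("FC2", "FC4", "FC6"))),
    list(mid_rho = 0,    ring = "T",  outer = c("T7", "T8"),
         inner = list(c("C1", "C3", "C5"), c("C2", "C4", "C6"))),
    list(mid_rho = 0.25, ring = "TP", outer = c("TP7", "TP8"),
         inner = list(c("CP1", "CP3", "CP5"), c("CP2", "CP4", "CP6"))),
    list(mid_rho = 0.5,  ring = "P",  outer = c("P7", "P8"),
         inner = list(c("P1", "P3", "P5"), c("P2", "P4", "P6"))),
    list(mid_rho = 0.75, ring = "PO", outer = c("PO7", "PO8"),
         inner = list(c("PO3"), c("PO4"))),
    list(mid_rho = 1,    ring = "O",  outer = c("O1", "O2"), inner = NULL))

  for (row in lateral_rows) {
    rang <- ring[[row$ring]]
    mid_ang <- if (rang <= 90) 0 else 180
    for (s in 1:2) {                      # 1 = left, 2 = right
      side <- if (s == 1) -1 else 1
      add(row$outer[s], 1, rang, side)
      inner <- row$inner[[s]]
      if (!is.null(row$inner)) {
        k <- length(inner)
        for (j in seq_len(k)) {
          f <- j / (k + 1)                # fraction midline -> ring
          # interpolate in the flat plane between midline point and ring point
          m <- c(row$mid_rho * sinpi(mid_ang / 180),
                 row$mid_rho * cospi(mid_ang / 180))
          r <- c(sinpi(rang / 180), cospi(rang / 180))
          p <- (1 - f) * m + f * r
          rho <- sqrt(sum(p^2))
          ang <- atan2(p[1], p[2]) * 180 / pi
          add(inner[j], rho, ang, side)
        }
      }
    }
  }
  # below-equator parasagittal electrodes
  add("P9", 1.25, 126, -1); add("P10", 1.25, 126, 1)

  df <- do.call(rbind, flat)
  # flat -> sphere: inclination = rho * 72 deg, azimuth = ang from front
  incl <- df$rho * 72 * pi / 180
  az <- df$ang * pi / 180
  out <- data.frame(
    name = df$name,
    x = sin(incl) * sin(az),
    y = sin(incl) * cos(az),
    z = cos(incl),
    fx = df$rho * sin(az),
    fy = df$rho * cos(az),
    type = "scalp",
    stringsAsFactors = FALSE)
  stopifnot(nrow(out) == 64L, !anyDuplicated(out$name))
  refs <- data.frame(
    name = c("A1", "A2"),
    x = c(-sin(100 * pi / 180), sin(100 * pi / 180)) * cos(5 * pi / 180),
    y = -sin(100 * pi / 180) * sin(5 * pi / 180),
    z = cos(100 * pi / 180),
    fx = c(-1.4, 1.4), fy = 0, type = "ref",
    stringsAsFactors = FALSE)
  rbind(out, refs)
}

#' Electrode adjacency graph
#'
#' Neighbourhood structure over the scalp electrodes used by the
#' mass-univariate significance rule (an effect must cover a connected set of
#' at least `min_cluster` sub-threshold electrodes). Two electrodes are
#' adjacent when their distance in the flat 2D projection of the layout is at
#' most `mult` times the median nearest-neighbour spacing. The graph is
#' returned explicitly so it can be inspected or replaced.
#'
#' @param layout layout data frame from [standard_layout_64()]; only rows
#'   with `type == "scalp"` are used.
#' @param mult distance threshold as a multiple of the median
#'   nearest-neighbour distance (default 1.5).
#' @return An object of class `electrode_adjacency`: a list with `names`
#'   (electrode names) and `edges` (two-column integer matrix of adjacent
#'   pairs, each pair once).
#' @export
electrode_adjacency <- function(layout = standard_layout_64(), mult = 1.5) {
  sc <- layout[layout$type == "scalp", , drop = FALSE]
  p <- as.matrix(sc[, c("fx", "fy")])
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  thr <- mult * stats::median(nn)
  idx <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
  structure(list(names = sc$name, edges = unname(idx)),
            class = "electrode_adjacency")
}

#' @export
print.electrode_adjacency <- function(x, ...) {
  cat("Electrode adjacency graph:", length(x$names), "electrodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

# connected components among a subset of vertices of the adjacency graph;
# returns a list of integer vectors (indices into adj$names)
adjacency_components <- function(adj, vertices) {
  vset <- sort(unique(vertices))
  if (!length(vset)) return(list())
  nb <- vector("list", length(adj$names))
  keep <- logical(length(adj$names)); keep[vset] <- TRUE
  for (k in seq_len(nrow(adj$edges))) {
    i <- adj$edges[k, 1L]; j <- adj$edges[k, 2L]
    if (keep[i] && keep[j]) {
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  seen <- logical(length(adj$names))
  comps <- list()
  for (v in vset) {
    if (seen[v]) next
    stack <- v; seen[v] <- TRUE; comp <- integer()
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, u)
      for (w in nb[[u]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
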