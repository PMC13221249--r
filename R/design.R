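#' @keywords internal
"_PACKAGE"

# Factor level conventions used throughout: the first level of each factor is
# coded -0.5 and the second +0.5. Cell order is beneficiary slowest, then
# magnitude, then time fastest, so serialized RDMs and cell tables are
# comparable across runs.
.factor_levels <- list(
  beneficiary = c("self", "other"),
  magnitude   = c("small", "large"),
  time        = c("immediate", "delayed")
)

.term_names <- c("(Intercept)", "ben", "mag", "tim",
                 "ben:mag", "ben:tim", "mag:tim", "ben:mag:tim")

#' Design cell table for the 2x2x2 prosocial reward design
#'
#' Returns the eight design cells in the package's fixed ordering
#' (beneficiary slowest, time fastest), with both string levels and the
#' -0.5/+0.5 numeric codes used by the statistical layer.
#'
#' @param factors character vector of factor names to cross (subset of
#'   `c("beneficiary", "magnitude", "time")`), in slowest-to-fastest order.
#' @return data.frame with one row per cell: string levels, coded columns
#'   (`ben`, `mag`, `tim` as applicable) and a `cell` index.
#' @export
cell_table <- function(factors = c("beneficiary", "magnitude", "time")) {
  stopifnot(all(factors %in% names(.factor_levels)))
  levs <- .factor_levels[factors]
  grid <- expand.grid(rev(levs), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, rev(seq_along(levs)), drop = FALSE]
  names(grid) <- factors
  code_of <- function(f, v) ifelse(v == .factor_levels[[f]][1], -0.5, +0.5)
  codes <- list(beneficiary = "ben", magnitude = "mag", time = "tim")
  for (f in factors) grid[[codes[[f]]]] <- code_of(f, grid[[f]])
  grid$cell <- seq_len(nrow(grid))
  grid
}

#' Full-factorial coded model matrix over the 8 design cells
#'
#' Columns: intercept, three main effects, three two-way interactions and the
#' three-way interaction, all under -0.5/+0.5 coding. The matrix is invertible,
#' so cell means and term coefficients are two parameterizations of the same
#' 8-vector.
#'
#' @return 8 x 8 numeric matrix with named columns.
#' @export
design_matrix_terms <- function() {
  ct <- cell_table()
  X <- cbind(1, ct$ben, ct$mag, ct$tim,
             ct$ben * ct$mag, ct$ben * ct$tim, ct$mag * ct$tim,
             ct$ben * ct$mag * ct$tim)
  colnames(X) <- .term_names
  rownames(X) <- paste(ct$beneficiary, ct$magnitude, ct$time, sep = ".")
  X
}

#' Convert term coefficients to the 8 cell means (and back)
#'
#' @param beta named or ordered numeric vector of 8 term coefficients
#'   (intercept, ben, mag, tim, ben:mag, ben:tim, mag:tim, ben:mag:tim).
#' @return numeric vector of 8 cell means in the package cell order.
#' @export
terms_to_cells <- function(beta) {
  stopifnot(length(beta) == 8L)
  if (!is.null(names(beta)) && all(.term_names %in% names(beta)))
    beta <- beta[.term_names]
  drop(design_matrix_terms() %*% as.numeric(beta))
}

#' @rdname terms_to_cells
#' @param mu numeric vector of 8 cell means in package cell order.
#' @export
cells_to_terms <- function(mu) {
  stopifnot(length(mu) == 8L)
  beta <- drop(solve(design_matrix_terms(), as.numeric(mu)))
  names(beta) <- .term_names
  beta
}

#' Schematic 62-channel scalp layout
#'
#' A 10-10-style montage with 60 scalp channels plus the two mastoids (M1, M2),
#' with schematic 2-D positions (nose up, x left-negative). Contains the ROI
#' channels Fz, FCz, Cz, CPz and Pz used for ERP and band-power scoring.
#'
#' @return data.frame with columns `name`, `x`, `y`.
#' @export
standard_layout <- function() {
  row <- function(names, y, xs) data.frame(name = names, x = xs, y = y)
  lat9 <- c(-1, -0.72, -0.45, -0.2, 0, 0.2, 0.45, 0.72, 1)
  out <- rbind(
    row(c("Fp1", "Fpz", "Fp2"), 0.95, c(-0.3, 0, 0.3)),
    row(c("AF7", "AF3", "AF4", "AF8"), 0.75, c(-0.6, -0.3, 0.3, 0.6)),
    row(c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"), 0.55, lat9),
    row(c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"), 0.28, lat9),
    row(c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"), 0, lat9),
    row(c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"), -0.28, lat9),
    row(c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"), -0.55, lat9),
    row(c("PO7", "PO3", "POz", "PO4", "PO8"), -0.75, c(-0.6, -0.3, 0, 0.3, 0.6)),
    row(c("O1", "Oz", "O2"), -0.92, c(-0.3, 0, 0.3)),
    row(c("M1", "M2"), -0.15, c(-1.15, 1.15))
  )
  rownames(out) <- NULL
  out
}

#' Names of scalp (non-mastoid) channels in a layout
#' @param layout data.frame as from [standard_layout()].
#' @keywords internal
scalp_channels <- function(layout) setdiff(layout$name, c("M1", "M2"))

#' Study design specification
#'
#' @param n_participants number of participants in a cohort.
#' @param n_trials_per_cell trials per design cell (8 cells).
#' @param sampling_rate Hz.
#' @param epoch_window numeric length 2, epoch start/end in ms relative to
#'   feedback onset.
#' @param layout channel layout data.frame (`name`, `x`, `y`); must contain the
#'   ROI channels Fz, FCz, Cz, CPz, Pz.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(n_participants = 40L,
                        n_trials_per_cell = 40L,
                        sampling_rate = 500,
                        epoch_window = c(-1500, 2000),
                        layout = standard_layout()) {
  stopifnot(n_participants >= 1, n_trials_per_cell >= 1,
            sampling_rate > 0, length(epoch_window) == 2,
            epoch_window[1] < epoch_window[2])
  if (anyDuplicated(layout$name))
    stop("duplicate channel names in layout")
  roi <- c("Fz", "FCz", "Cz", "CPz", "Pz")
  if (!all(roi %in% layout$name))
    stop("layout must contain ROI channels: ",
         paste(setdiff(roi, layout$name), collapse = ", "))
  structure(list(n_participants = as.integer(n_participants),
                 n_trials_per_cell = as.integer(n_trials_per_cell),
                 sampling_rate = sampling_rate,
                 epoch_window = epoch_window,
                 layout = layout),
            class = "design_spec")
}
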