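# Turnover-boundary estimation: a smooth probability-of-turnover surface
# over (s_Y, s_new) per epsilon slice, with the 0.5-probability contour
# extracted as the maintenance/turnover boundary.

#' Estimate turnover boundaries in parameter space
#'
#' Fits a smooth probability-of-turnover surface over `(s_Y, s_new)` for
#' each epsilon slice of a sweep table and returns the 0.5-probability
#' contour as polyline vertices. Two smoothers are available:
#'
#' * `"kernel"` (default, self-contained): local-linear smoothing of the
#'   binary outcome with a Gaussian product kernel. Local-linear fits
#'   remove the boundary bias of plain kernel averaging; bandwidths
#'   default to 1.5 times Scott's rule (`sd * n^(-1/6)`) per dimension.
#' * `"gam"`: a penalized-spline logistic fit
#'   (`mgcv::gam(outcome ~ s(s_Y, s_new), family = binomial)`).
#'
#' Both smoothers weight duplicated records identically to repeated
#' observations, so duplicating the input rescales weights without moving
#' the contour (at fixed bandwidth). When the table's epsilon values are
#' continuous rather than a few discrete levels, the kernel smoother adds
#' epsilon as a third kernel dimension and evaluates the surface at each
#' requested slice.
#'
#' Contour vertices within one bandwidth (one grid cell for `"gam"`) of
#' the evaluation-range boundary are flagged in the `edge` column: there
#' the smoother extrapolates from one-sided data and the boundary
#' location is not reliably identified.
#'
#' @param records A sweep table (as from [run_sweep()]) with columns
#'   `s_Y`, `s_new`, `outcome` and optionally `epsilon`; rows with `NA`
#'   outcome are dropped.
#' @param epsilon_slices Numeric epsilon values at which to extract
#'   boundaries. Defaults to the distinct epsilon values in `records`
#'   when there are at most eight, else quintiles of the sampled range.
#' @param grid_n Grid resolution per axis for contour extraction
#'   (default 51).
#' @param method `"kernel"` or `"gam"`.
#' @param bandwidth Optional kernel bandwidth(s); a scalar or a vector of
#'   one value per kernel dimension. Ignored for `"gam"`.
#' @param range_s Evaluation range for both axes; defaults to the data
#'   range.
#' @return A tibble of class `sd_boundary` with columns `epsilon`,
#'   `contour` (polyline id within slice), `s_Y`, `s_new`, `edge`. The
#'   fitted probability surfaces are kept in the `surfaces` attribute for
#'   plotting.
#' @examples
#' set.seed(1)
#' rec <- tibble::tibble(s_Y = runif(400, 0, 0.05),
#'                       s_new = runif(400, 0, 0.05),
#'                       epsilon = 0,
#'                       outcome = as.integer(s_new > s_Y))
#' b <- estimate_boundary(rec)
#' head(b)
#' @export
estimate_boundary <- function(records, epsilon_slices = NULL, grid_n = 51L,
                              method = c("kernel", "gam"), bandwidth = NULL,
                              range_s = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records),
            all(c("s_Y", "s_new", "outcome") %in% names(records)))
  rec <- records[!is.na(records$outcome), , drop = FALSE]
  if (!"epsilon" %in% names(rec)) rec$epsilon <- 0
  if (nrow(rec) < 50L) {
    warning("fewer than 50 usable records; boundary estimate may be unstable")
  }
  classes <- unique(rec$outcome)
  if (length(classes) < 2L) {
    stop("single-class input: all outcomes are ", classes,
         "; no boundary is estimable")
  }

  eps_vals <- sort(unique(rec$epsilon))
  discrete <- length(eps_vals) <= 8L
  if (is.null(epsilon_slices)) {
    epsilon_slices <- if (discrete) eps_vals else {
      stats::quantile(rec$epsilon, probs = seq(0.1, 0.9, by = 0.2),
                      names = FALSE)
    }
  }
  if (is.null(range_s)) {
    range_s <- range(c(rec$s_Y, rec$s_new))
  }
  gx <- seq(range_s[1], range_s[2], length.out = grid_n)
  gy <- gx
  cellw <- diff(range_s) / (grid_n - 1)

  # local-linear kernel regression of the 0/1 outcome on (s_Y, s_new),
  # optionally weighted by an epsilon kernel; returns the surface matrix
  loclin <- function(dat, we, h) {
    p <- matrix(NA_real_, grid_n, grid_n)
    y <- dat$outcome
    for (i in seq_len(grid_n)) {
      dx <- dat$s_Y - gx[i]
      kx <- exp(-0.5 * (dx / h[1])^2) * we
      for (j in seq_len(grid_n)) {
        dy <- dat$s_new - gy[j]
        w <- kx * exp(-0.5 * (dy / h[2])^2)
        x_mat <- cbind(1, dx, dy)
        xtw <- t(x_mat * w)
        beta <- tryCatch(solve(xtw %*% x_mat, xtw %*% y),
                         error = function(e) NULL)
        p[i, j] <- if (is.null(beta)) {
          sum(w * y) / max(sum(w), .Machine$double.xmin)
        } else beta[1]
      }
    }
    p
  }

  fit_slice <- function(eps) {
    sub <- rec[abs(rec$epsilon - eps) < 1e-12, , drop = FALSE]
    use_3d <- !discrete || nrow(sub) == 0L
    dat <- if (use_3d) rec else sub
    if (length(unique(dat$outcome)) < 2L) {
      # surface is flat in this slice; no contour to extract
      return(list(p = matrix(mean(dat$outcome), grid_n, grid_n),
                  margin = cellw))
    }
    if (method == "gam") {
      if (!requireNamespace("mgcv", quietly = TRUE)) {
        stop("method = \"gam\" requires the mgcv package")
      }
      form <- if (use_3d) outcome ~ s(s_Y, s_new, epsilon) else
        outcome ~ s(s_Y, s_new)
      fit <- mgcv::gam(form, family = stats::binomial(), data = dat)
      nd <- expand.grid(s_Y = gx, s_new = gy)
      nd$epsilon <- eps
      p <- matrix(stats::predict(fit, nd, type = "response"),
                  grid_n, grid_n)
      list(p = p, margin = cellw)
    } else {
      ndim <- if (use_3d) 3L else 2L
      h <- bandwidth
      if (is.null(h)) {
        n <- nrow(dat)
        h <- 1.5 * c(stats::sd(dat$s_Y), stats::sd(dat$s_new),
                     if (use_3d) stats::sd(dat$epsilon)) * n^(-1 / 6)
        h <- pmax(h, cellw)  # never narrower than a grid cell
      } else {
        h <- rep_len(h, ndim)
      }
      we <- if (use_3d) exp(-0.5 * ((dat$epsilon - eps) / h[3])^2) else
        rep(1, nrow(dat))
      list(p = loclin(dat, we, h), margin = max(h[1], h[2]))
    }
  }

  out <- purrr::map(epsilon_slices, function(eps) {
    fit <- fit_slice(eps)
    cl <- grDevices::contourLines(gx, gy, fit$p, levels = 0.5)
    tb <- if (length(cl) == 0L) {
      tibble::tibble(epsilon = numeric(0), contour = integer(0),
                     s_Y = numeric(0), s_new = numeric(0),
                     edge = logical(0))
    } else {
      purrr::imap(cl, function(cc, i) {
        tibble::tibble(epsilon = eps, contour = as.integer(i),
                       s_Y = cc$x, s_new = cc$y,
                       edge = cc$x < range_s[1] + fit$margin |
                         cc$x > range_s[2] - fit$margin |
                         cc$y < range_s[1] + fit$margin |
                         cc$y > range_s[2] - fit$margin)
      }) |> dplyr::bind_rows()
    }
    list(contours = tb, surface = fit$p)
  })

  contours <- dplyr::bind_rows(purrr::map(out, "contours"))
  surfaces <- purrr::map(out, "surface")
  names(surfaces) <- as.character(epsilon_slices)
  structure(contours,
            class = c("sd_boundary", class(contours)),
            grid_x = gx, grid_y = gy, surfaces = surfaces,
            method = method)
}

#' Plot estimated turnover boundaries
#'
#' One 0.5-probability contour path per (epsilon, contour) pair, in the
#' `(s_Y, s_new)` plane. The turnover region generally lies on the
#' high-`s_new` side of each line. Edge-flagged vertices (see
#' [estimate_boundary()]) are drawn dotted.
#'
#' @param object An `sd_boundary` object from [estimate_boundary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sd_boundary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$s_Y, .data$s_new,
                                   colour = factor(.data$epsilon),
                                   group = interaction(.data$epsilon,
                                                       .data$contour))) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$edge)) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dotted"),
                                   guide = "none") +
    ggplot2::labs(x = expression(s[Y]), y = expression(s[new]),
                  colour = expression(epsilon)) +
    ggplot2::theme_minimal()
}
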