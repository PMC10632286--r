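#' Study-level realignment analysis
#'
#' Realignment and between-method difference matrices, their Euler
#' decomposition, the statistical battery (Shapiro-Wilk normality, paired
#' two-tailed t-tests, intraclass correlation, Pearson correlation,
#' exponential cartilage-age fits), and the study report that assembles
#' them across a cohort planned with several segmentation sources.
#'
#' @name realignment-analysis
NULL

#' Realignment transform of a planned bone
#'
#' The rotational and translational difference of the distal fragment
#' relative to the proximal fragment: `M = M_prox^-1 x M_dist`.
#'
#' @param m_prox,m_dist joint-end registration transforms.
#' @return A `rigid_transform`.
#' @export
realignment <- function(m_prox, m_dist) relative(m_prox, m_dist)

#' Between-method realignment difference
#'
#' For the same bone planned from two segmentation sources,
#' `M_S1-S2 = M_S1^-1 x M_S2`, its Euler decomposition, and the Euclidean
#' translational and rotational distances (Delta T, Phi R) between the two
#' methods' realignment components.
#'
#' @param m_method1,m_method2 realignment transforms of the same bone from
#'   two methods.
#' @return List with `difference` (`rigid_transform`), `decomposition`
#'   (`euler_decomposition` of the difference), `delta_T` (mm), `phi_R`
#'   (radians).
#' @export
method_difference <- function(m_method1, m_method2) {
  diff <- relative(m_method1, m_method2)
  d1 <- decompose_euler(m_method1)
  d2 <- decompose_euler(m_method2)
  dd <- realignment_distance(d1, d2)
  list(difference = diff, decomposition = decompose_euler(diff),
       delta_T = dd[["delta_T"]], phi_R = dd[["phi_R"]])
}

#' Intraclass correlation: two-way random, absolute agreement, single measures
#'
#' From the standard mean-square decomposition of a subjects x raters table:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`, with MS_R the
#' between-subject, MS_C the between-rater, and MS_E the residual mean
#' square. A table with zero total variance is perfect agreement (1.0, with
#' a warning). Missing cells are an error.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (>= 2 of each).
#' @return The ICC, bounded in [-1, 1].
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells in the ratings table", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  gm <- mean(ratings)
  if (sum((ratings - gm)^2) == 0) {
    warning("zero total variance; ICC defined as 1")
    return(1.0)
  }
  rm <- rowMeans(ratings); cm <- colMeans(ratings)
  msr <- k * sum((rm - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sse <- sum((ratings - outer(rm, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Univariate and paired test wrappers
#'
#' Thin wrappers around the standard tests, returning (statistic, p) pairs:
#' Shapiro-Wilk normality, two-tailed paired t on the difference vector, and
#' Pearson correlation.
#'
#' @param x,y numeric samples.
#' @name test-battery
NULL

#' @rdname test-battery
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3) stop("Shapiro-Wilk needs n >= 3", call. = FALSE)
  s <- stats::shapiro.test(x)
  c(W = unname(s$statistic), p = s$p.value)
}

#' @rdname test-battery
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("paired t needs >= 2 pairs of equal length", call. = FALSE)
  d <- x - y
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    if (all(abs(d) <= 1e-12 * max(abs(x), 1))) return(c(t = 0, p = 1))
    stop("zero-variance difference vector: t statistic undefined", call. = FALSE)
  }
  s <- stats::t.test(x, y, paired = TRUE)
  c(t = unname(s$statistic), p = s$p.value)
}

#' @rdname test-battery
#' @export
pearson <- function(x, y) {
  if (length(x) < 3) stop("correlation needs n >= 3", call. = FALSE)
  s <- stats::cor.test(x, y, method = "pearson")
  c(R = unname(s$estimate), p = s$p.value)
}

#' Exponential fit of relative cartilage volume against age
#'
#' Least squares on `log(rcv) ~ age`, i.e. `rcv ~ a * exp(b * age)`.
#' Decreasing cartilage with age gives `b < 0`.
#'
#' @param age years.
#' @param rcv relative cartilage volumes (> 0).
#' @return Named vector `c(a = , b = )`.
#' @export
exp_fit <- function(age, rcv) {
  if (length(age) < 3) stop("exponential fit needs n >= 3", call. = FALSE)
  if (any(rcv <= 0)) stop("rcv values must be positive", call. = FALSE)
  fit <- stats::lm(log(rcv) ~ age)
  c(a = exp(unname(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]))
}

# reference residual surgical errors used for the clinical-relevance
# comparison (total rotation, degrees; total translation, mm)
REFERENCE_RESIDUALS <- list(rotation_deg = c(mean = 5.6, sd = 4.2),
                            translation_mm = c(mean = 2.0, sd = 1.4))

#' Assemble a study report across cases and segmentation methods
#'
#' Takes one realignment per case x method (a `planning_result` or a bare
#' realignment `rigid_transform`), decomposes each into translations and
#' Euler angles, and produces: per-case rows; per-method summaries; per
#' method-pair difference summaries (Delta T, Phi R and component
#' differences); per-component ICC across methods; Shapiro-Wilk checks and
#' paired t-tests on the total T and R; and, when `planning_result`s are
#' given, plane-location/orientation comparisons (Delta Z, psi). Cases
#' missing any requested method are excluded with a warning.
#'
#' @param cases named list (one element per case) of named lists (one
#'   element per method, e.g. CTb/MRb/MRbc).
#' @param methods method names to include; defaults to those of the first
#'   case.
#' @return A `study_report` list.
#' @export
build_study_report <- function(cases, methods = NULL) {
  if (length(cases) == 0) stop("no cases", call. = FALSE)
  if (is.null(methods)) methods <- names(cases[[1]])
  if (length(methods) < 2)
    stop("need >= 2 methods to compare", call. = FALSE)
  complete <- vapply(cases, function(cs) all(methods %in% names(cs)), logical(1))
  if (!all(complete)) {
    warning("excluding incomplete case(s): ",
            paste(names(cases)[!complete], collapse = ", "))
    cases <- cases[complete]
  }
  if (length(cases) == 0) stop("no complete cases", call. = FALSE)

  get_realign <- function(x) {
    if (inherits(x, "planning_result")) x$realignment else as_rigid(x)
  }
  rows <- do.call(rbind, lapply(names(cases), function(id) {
    do.call(rbind, lapply(methods, function(m) {
      d <- decompose_euler(get_realign(cases[[id]][[m]]))
      data.frame(case = id, method = m,
                 dx = d$dx, dy = d$dy, dz = d$dz,
                 phi_x = d$phi_x, phi_y = d$phi_y, phi_z = d$phi_z,
                 T = d$T, R = d$R)
    }))
  }))

  method_summary <- do.call(rbind, lapply(methods, function(m) {
    sub <- rows[rows$method == m, ]
    data.frame(method = m, mean_T = mean(sub$T), sd_T = stats::sd(sub$T),
               mean_R = mean(sub$R), sd_R = stats::sd(sub$R))
  }))

  pairs <- utils::combn(methods, 2, simplify = FALSE)
  comp_cols <- c("dx", "dy", "dz", "phi_x", "phi_y", "phi_z")
  pair_summary <- do.call(rbind, lapply(pairs, function(p) {
    diffs <- lapply(names(cases), function(id)
      method_difference(get_realign(cases[[id]][[p[1]]]),
                        get_realign(cases[[id]][[p[2]]])))
    dT <- vapply(diffs, `[[`, numeric(1), "delta_T")
    pR <- vapply(diffs, `[[`, numeric(1), "phi_R")
    a <- rows[rows$method == p[1], ]; b <- rows[rows$method == p[2], ]
    out <- data.frame(pair = paste(p, collapse = "-"),
                      mean_delta_T = mean(dT), sd_delta_T = stats::sd(dT),
                      mean_phi_R = mean(pR), sd_phi_R = stats::sd(pR))
    for (cc in comp_cols) {
      out[[paste0("mean_d_", cc)]] <- mean(a[[cc]] - b[[cc]])
      out[[paste0("sd_d_", cc)]] <- stats::sd(a[[cc]] - b[[cc]])
    }
    out
  }))

  icc <- do.call(rbind, lapply(c(comp_cols, "T", "R"), function(cc) {
    tab <- sapply(methods, function(m) rows[rows$method == m, cc])
    data.frame(component = cc, icc = icc_agreement(as.matrix(tab)))
  }))

  tests <- do.call(rbind, lapply(pairs, function(p) {
    a <- rows[rows$method == p[1], ]; b <- rows[rows$method == p[2], ]
    do.call(rbind, lapply(c("T", "R"), function(cc) {
      d <- a[[cc]] - b[[cc]]
      sw <- if (length(d) >= 3)
        tryCatch(shapiro_wilk(d), error = function(e) c(W = NA, p = NA))
      else c(W = NA, p = NA)
      tt <- tryCatch(paired_t(a[[cc]], b[[cc]]),
                     error = function(e) c(t = NA, p = NA))
      data.frame(pair = paste(p, collapse = "-"), component = cc,
                 shapiro_W = sw[["W"]], shapiro_p = sw[["p"]],
                 t = tt[["t"]], t_p = tt[["p"]])
    }))
  }))

  have_planes <- all(vapply(cases, function(cs)
    all(vapply(cs[methods], inherits, logical(1), "planning_result")),
    logical(1)))
  plane_comparison <- NULL
  if (have_planes) {
    plane_comparison <- do.call(rbind, lapply(pairs, function(p) {
      pc <- lapply(names(cases), function(id)
        compare_planes(cases[[id]][[p[1]]], cases[[id]][[p[2]]]))
      dz <- vapply(pc, `[[`, numeric(1), "delta_z")
      pa <- vapply(pc, `[[`, numeric(1), "psi_a")
      pz <- vapply(pc, `[[`, numeric(1), "psi_z")
      data.frame(pair = paste(p, collapse = "-"),
                 mean_abs_delta_z = mean(abs(dz)), sd_abs_delta_z = stats::sd(abs(dz)),
                 mean_abs_psi_a = mean(abs(pa)), sd_abs_psi_a = stats::sd(abs(pa)),
                 mean_abs_psi_z = mean(abs(pz)), sd_abs_psi_z = stats::sd(abs(pz)))
    }))
  }

  structure(list(rows = rows, method_summary = method_summary,
                 pair_summary = pair_summary, icc = icc, tests = tests,
                 plane_comparison = plane_comparison,
                 reference_residuals = REFERENCE_RESIDUALS),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n  cases:", length(unique(x$rows$case)),
      " methods:", paste(unique(x$rows$method), collapse = ", "), "\n")
  cat("  pair summaries:\n")
  print(x$pair_summary[, 1:5], row.names = FALSE)
  cat("  ICC by component:\n")
  print(x$icc, row.names = FALSE)
  invisible(x)
}
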