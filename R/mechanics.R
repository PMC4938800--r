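#' Named structure-vector definition
#'
#' Vectors used to quantify hinge and interfacial motions: a `line` through
#' two Calpha anchors, or a `plane_normal` (normalized cross product of the
#' two edge vectors of a three-Calpha anchor triangle, orientation fixed by
#' anchor order). Definitions are configuration data, not code: anchors are
#' editable residue ids.
#'
#' @param name vector name.
#' @param kind `"line"` or `"plane_normal"`.
#' @param chain chain id of the anchors.
#' @param resnos 2 (line) or 3 (plane_normal) anchor residue numbers.
#' @param signed should angle series using this pair carry a sign.
#' @param sign_ref name of the vector definition supplying the sign
#'   reference direction.
#' @return object of class `vector_def`.
#' @export
vector_def <- function(name, kind = c("line", "plane_normal"), chain,
                       resnos, signed = FALSE, sign_ref = NULL) {
  kind <- match.arg(kind)
  need <- if (kind == "line") 2L else 3L
  if (length(resnos) != need)
    stop(kind, " needs ", need, " anchor residues")
  if (anyDuplicated(resnos)) stop("anchor residues must be distinct")
  structure(list(name = name, kind = kind, chain = chain,
                 resnos = as.integer(resnos), signed = signed,
                 sign_ref = sign_ref),
            class = "vector_def")
}

#' Resolve vector definitions on one conformer's Calpha coordinates
#'
#' @param coords n_res x 3 Calpha matrix with `chain:resno` rownames.
#' @param defs list of [vector_def()].
#' @return named list of unit vectors.
#' @export
resolve_vectors <- function(coords, defs) {
  keys <- rownames(coords)
  out <- lapply(defs, function(d) {
    want <- paste(d$chain, d$resnos, sep = ":")
    m <- match(want, keys)
    if (anyNA(m))
      stop("anchor residue(s) missing for vector ", d$name, ": ",
           paste(want[is.na(m)], collapse = ", "))
    p <- coords[m, , drop = FALSE]
    if (d$kind == "line") {
      unit(p[2, ] - p[1, ])
    } else {
      n <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
      if (sqrt(sum(n^2)) < 1e-8)
        stop("collinear anchors for plane normal ", d$name)
      unit(n)
    }
  })
  names(out) <- vapply(defs, `[[`, "", "name")
  out
}

angle_between <- function(v1, v2, sign_vec = NULL) {
  th <- rad2deg(acos(min(1, max(-1, sum(v1 * v2)))))
  if (!is.null(sign_vec)) {
    s <- sum(cross3(v1, v2) * sign_vec)
    if (s < 0) th <- -th
  }
  th
}

# N x n_res x 3 CA coordinates + mean structure of a source (ensemble or
# single-PC pseudo-trajectory)
source_ca <- function(source) {
  if (inherits(source, "ConformerEnsemble")) {
    ca <- ensemble_ca(source)
    mu <- apply(ca$coords, c(2, 3), mean)
    rownames(mu) <- ca$keys
    list(coords = ca$coords, keys = ca$keys, mean = mu)
  } else if (inherits(source, "pc_trajectory")) {
    mu <- source$mean
    rownames(mu) <- source$keys
    list(coords = source$coords, keys = source$keys, mean = mu)
  } else {
    stop("source must be a ConformerEnsemble or pc_trajectory")
  }
}

#' Difference-angle series between a vector pair
#'
#' Per conformer, the angle between the two named vectors minus the same
#' angle in the ensemble-average structure (so the average structure reads
#' 0 degrees). Unsigned by default; signed when the pair definition (or the
#' `signed`/`sign_ref` arguments) supplies a sign reference vector, in which
#' case the sign is that of the triple product (v1 x v2) . sign_ref.
#'
#' @param source `ConformerEnsemble` or [pc_trajectory()].
#' @param pair character of the two vector names.
#' @param defs list of [vector_def()] containing the pair (and any sign
#'   reference).
#' @param signed override the pair's sign policy.
#' @param sign_ref override the sign-reference vector name.
#' @return object of class `angle_series`: numeric degrees with attributes
#'   `pair`, `reference_angle`, `source`.
#' @export
angle_series <- function(source, pair, defs, signed = NULL, sign_ref = NULL) {
  stopifnot(length(pair) == 2)
  nm <- vapply(defs, `[[`, "", "name")
  d1 <- defs[[match(pair[1], nm)]]
  d2 <- defs[[match(pair[2], nm)]]
  if (is.null(d1) || is.null(d2))
    stop("vector pair not found among definitions: ",
         paste(pair, collapse = ", "))
  signed <- signed %||% (isTRUE(d1$signed) || isTRUE(d2$signed))
  sref_name <- sign_ref %||% d1$sign_ref %||% d2$sign_ref
  if (signed && is.null(sref_name))
    stop("signed angles need a sign-reference vector definition")
  use <- Filter(Negate(is.null), list(d1, d2,
                                      if (signed) defs[[match(sref_name, nm)]]))
  src <- source_ca(source)
  ref_v <- resolve_vectors(src$mean, use)
  sref <- if (signed) ref_v[[sref_name]] else NULL
  ref_angle <- angle_between(ref_v[[pair[1]]], ref_v[[pair[2]]], sref)
  N <- dim(src$coords)[1]
  ang <- numeric(N)
  for (r in seq_len(N)) {
    co <- src$coords[r, , , drop = TRUE]
    rownames(co) <- src$keys
    v <- resolve_vectors(co, use)
    sv <- if (signed) v[[sref_name]] else NULL
    ang[r] <- angle_between(v[[pair[1]]], v[[pair[2]]], sv) - ref_angle
  }
  structure(ang, class = "angle_series", pair = pair,
            reference_angle = ref_angle,
            source = if (inherits(source, "pc_trajectory"))
              paste0("PC", source$k) else "ensemble")
}

#' Width (population SD) of a difference-angle series
#' @param s `angle_series` (or numeric degrees).
#' @return degrees.
#' @export
angle_sigma <- function(s) pop_sd(as.numeric(s))

#' Mechanical amplification between two angle series
#'
#' Ratio of the distal to the proximal angular width,
#' sigma_distal / sigma_proximal.
#'
#' @param distal,proximal `angle_series`.
#' @return unitless ratio.
#' @export
amplification <- function(distal, proximal) {
  sp <- angle_sigma(proximal)
  if (sp <= 0) stop("proximal series has zero width")
  angle_sigma(distal) / sp
}

# histogram model forms (Fig-style single and symmetric double Gaussian)
gauss_single <- function(x, a, b, x0) a * exp(-0.5 * ((x - x0) / b)^2)
gauss_double <- function(x, a, b, x0)
  a * (exp(-0.5 * ((x - x0) / b)^2) + exp(-0.5 * ((x + x0) / b)^2))

# Freedman-Diaconis bin count
fd_bins <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr == 0) return(10L)
  max(5L, ceiling(diff(range(x)) / (2 * iqr * length(x)^(-1 / 3))))
}

#' Fit single- and symmetric-double-Gaussian models to an angle histogram
#'
#' Histograms the series and least-squares fits (on the bin centers) the
#' single form `y = a exp(-0.5 ((x - x0)/b)^2)` and the symmetric double
#' form `y = a [exp(-0.5 ((x - x0)/b)^2) + exp(-0.5 ((x + x0)/b)^2)]`,
#' reporting both parameter sets with R^2. A bimodal (two-state) well is
#' flagged when the double fit's R^2 exceeds the single fit's.
#'
#' @param s `angle_series` (degrees).
#' @param n_bins histogram bins (default Freedman-Diaconis).
#' @return object of class `gaussian_fit`: `single`, `double` (each
#'   list(a, b, x0, r2) or NULL on non-convergence), `preferred`
#'   (`"single"` or `"double"`), `histogram`.
#' @export
fit_angle_models <- function(s, n_bins = NULL) {
  x <- as.numeric(s)
  n_bins <- n_bins %||% fd_bins(x)
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  d <- data.frame(x = h$mids, y = h$counts)
  sst <- sum((d$y - mean(d$y))^2)
  r2 <- function(fit) 1 - sum(residuals(fit)^2) / sst
  safe_fit <- function(formula, start, lower) {
    tryCatch({
      fit <- minpack.lm::nlsLM(formula, data = d, start = start,
                               lower = lower,
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      c(as.list(coef(fit)), r2 = r2(fit))
    }, error = function(e) {
      warning("fit did not converge: ", conditionMessage(e))
      NULL
    })
  }
  w <- pop_sd(x)
  single <- safe_fit(y ~ gauss_single(x, a, b, x0),
                     list(a = max(d$y), b = w, x0 = mean(x)),
                     c(a = 0, b = 1e-6, x0 = -Inf))
  double <- safe_fit(y ~ gauss_double(x, a, b, x0),
                     list(a = max(d$y) / 2, b = max(w / 2, 1e-3),
                          x0 = max(w, 1e-3)),
                     c(a = 0, b = 1e-6, x0 = 0))
  preferred <- if (!is.null(double) && !is.null(single) &&
                   double$r2 > single$r2) "double" else "single"
  structure(list(single = single, double = double, preferred = preferred,
                 histogram = d),
            class = "gaussian_fit")
}

#' Torsional stiffness from an angular width
#'
#' kappa = k_B T / sigma_rad^2 for a harmonic torsional well whose angular
#' fluctuation has SD `width` degrees; k_B T = 4.114 pN nm at the default
#' 300 K (the commonly quoted room-temperature value).
#'
#' @param width angular width, degrees (> 0). Use the single fit's `b` for
#'   a one-state estimate or the double fit's per-state `b` for a two-state
#'   estimate.
#' @param temperature Kelvin.
#' @param model label recording where the width came from
#'   (`"one_state"`/`"two_state"`).
#' @return object of class `stiffness_estimate`: `kappa_pn_nm`,
#'   `width_deg`, `temperature`, `model`.
#' @export
torsional_stiffness <- function(width, temperature = 300,
                                model = c("one_state", "two_state")) {
  model <- match.arg(model)
  if (width <= 0) stop("width must be positive")
  kbt <- 4.114 / 300 * temperature # pN nm
  structure(list(kappa_pn_nm = kbt / deg2rad(width)^2, width_deg = width,
                 temperature = temperature, model = model),
            class = "stiffness_estimate")
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  cat(sprintf("torsional stiffness: %.0f pN nm (%s, width %.2f deg, %g K)\n",
              x$kappa_pn_nm, x$model, x$width_deg, x$temperature))
  invisible(x)
}

#' Classify the coupling relation between two angle series
#'
#' Fits three candidate forms to (x, y): linear `y = s x + c`, a saturating
#' end-state form `y = y0 + clamp(s (x - x0), -L, +L)` (plateau / linear /
#' plateau), and parabolic `y = c x^2 + d` (motion constrained by an elastic
#' well), and selects by adjusted R^2.
#'
#' @param x,y equal-length `angle_series` (degrees).
#' @return object of class `coupling_relation`: `winner`, `fits` (per-form
#'   parameters, `r2`, `adj_r2`; linear also reports the slope SE).
#' @export
coupling_relation <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("series differ in length")
  n <- length(x)
  adj <- function(r2, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)
  sst <- sum((y - mean(y))^2)
  fits <- list()

  lin <- lm(y ~ x)
  slin <- suppressWarnings(summary(lin)) # exact fits are legitimate here
  fits$linear <- list(slope = unname(coef(lin)[2]),
                      slope_se = slin$coefficients[2, 2],
                      intercept = unname(coef(lin)[1]),
                      r2 = slin$r.squared)
  fits$linear$adj_r2 <- adj(fits$linear$r2, 1)

  par_ <- lm(y ~ I(x^2))
  fits$parabolic <- list(c = unname(coef(par_)[2]),
                         intercept = unname(coef(par_)[1]),
                         r2 = suppressWarnings(summary(par_))$r.squared)
  fits$parabolic$adj_r2 <- adj(fits$parabolic$r2, 1)

  es <- tryCatch({
    st <- list(s = unname(coef(lin)[2]), L = max(abs(y - mean(y))),
               x0 = 0, y0 = mean(y))
    fit <- minpack.lm::nlsLM(
      y ~ y0 + pmin(pmax(s * (x - x0), -L), L),
      data = data.frame(x = x, y = y), start = st,
      lower = c(s = -Inf, L = 1e-9, x0 = -Inf, y0 = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    r2 <- 1 - sum(residuals(fit)^2) / sst
    c(as.list(coef(fit)), r2 = r2, adj_r2 = adj(r2, 4))
  }, error = function(e) NULL)
  fits$end_state <- es

  adj_all <- vapply(fits, function(f) if (is.null(f)) -Inf else f$adj_r2, 0)
  structure(list(winner = names(which.max(adj_all)), fits = fits),
            class = "coupling_relation")
}
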