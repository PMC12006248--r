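## Quasi-static conduction solve for paired needle electrodes.
##
## The pulse amplitude sets the field that decides cell kill, so the model is
## the stationary conduction problem div(sigma grad phi) = 0 with Dirichlet
## data +V/2 / -V/2 on the two electrode surfaces and (by default) zero-flux
## outer boundaries. Discretized on a regular lattice with a 5/7-point stencil
## and solved by red-black SOR (compiled kernel).

grid_axes <- function(domain) {
  h <- domain$grid_step
  lapply(domain$bounding_box, function(L) {
    n <- max(3L, round(L / h) + 1L)
    (seq_len(n) - (n + 1) / 2) * h   # symmetric about 0 = electrode midpoint
  })
}

## Conductivity per cell from the region list (later regions override earlier).
build_sigma <- function(domain, axes) {
  dims <- vapply(axes, length, 1L)
  if (!length(domain$regions)) return(domain$conductivity)
  d3 <- length(axes) == 3L
  sig <- array(domain$conductivity, dim = dims)
  X <- axes[[1]][slice.index(sig, 1)]
  Y <- axes[[2]][slice.index(sig, 2)]
  Z <- if (d3) axes[[3]][slice.index(sig, 3)] else 0
  half <- domain$bounding_box / 2
  for (r in domain$regions) {
    ctr <- r$center %||% rep(0, length(axes))
    if (any(abs(ctr) > half[seq_along(ctr)]))
      stop("region center outside bounding box", call. = FALSE)
    inside <- switch(r$shape,
      sphere = (X - ctr[1])^2 + (Y - ctr[2])^2 +
        (if (d3) (Z - ctr[3])^2 else 0) <= r$radius^2,
      cylinder = {
        m <- (X - ctr[1])^2 + (Y - ctr[2])^2 <= r$radius^2
        if (d3 && !is.null(r$height)) m & abs(Z - ctr[3]) <= r$height / 2 else m
      },
      slab = {
        ax <- switch(r$axis %||% "z", x = X, y = Y, z = if (d3) Z else Y)
        ax >= r$from & ax <= r$to
      })
    sig[inside] <- r$conductivity
  }
  sig
}

## Dirichlet mask/value arrays for the two needles (axes along z in 3-D).
electrode_dirichlet <- function(electrodes, axes) {
  dims <- vapply(axes, length, 1L)
  d3 <- length(axes) == 3L
  rad <- electrodes$diameter / 2
  half_exp <- electrodes$exposure / 2
  phi <- array(0, dim = dims)
  X <- axes[[1]][slice.index(phi, 1)]
  Y <- axes[[2]][slice.index(phi, 2)]
  inplane_p <- (X - electrodes$spacing / 2)^2 + Y^2 <= rad^2
  inplane_m <- (X + electrodes$spacing / 2)^2 + Y^2 <= rad^2
  if (d3) {
    Z <- axes[[3]][slice.index(phi, 3)]
    span <- abs(Z) <= half_exp
    inplane_p <- inplane_p & span
    inplane_m <- inplane_m & span
  }
  if (any(inplane_p & inplane_m))
    stop("invalid geometry: electrode cells overlap", call. = FALSE)
  if (!any(inplane_p) || !any(inplane_m))
    stop("invalid geometry: electrode not resolved on the grid", call. = FALSE)
  v2 <- electrodes$applied_voltage / 2
  phi[inplane_p] <- v2
  phi[inplane_m] <- -v2
  list(fixed = inplane_p | inplane_m, phi = phi)
}

## Shortley-Weller cut-cell tables: for free cells whose stencil legs cross
## the true electrode surface, the fractional leg length theta (in units of
## h) and the surface potential per direction (-x,+x,-y,+y,-z,+z). Without
## this, the rasterized conductor's effective radius is biased by O(h) and
## the whole field carries a systematic scale error.
electrode_cut_cells <- function(electrodes, axes, fixed, theta_min = 0.05) {
  dims <- vapply(axes, length, 1L)
  n <- prod(dims)
  h <- axes[[1]][2] - axes[[1]][1]
  d3 <- length(axes) == 3L
  a <- electrodes$diameter / 2
  half_exp <- electrodes$exposure / 2
  v2 <- electrodes$applied_voltage / 2

  tmp <- array(0L, dim = dims)
  X <- as.vector(axes[[1]][slice.index(tmp, 1)])
  Y <- as.vector(axes[[2]][slice.index(tmp, 2)])
  Z <- if (d3) as.vector(axes[[3]][slice.index(tmp, 3)]) else rep(0, n)

  theta_full <- NULL; bval_full <- NULL; cand_all <- NULL
  for (sgn in c(1, -1)) {
    xe <- sgn * electrodes$spacing / 2
    ve <- sgn * v2
    dx <- X - xe; dy <- Y
    near_side <- sqrt(dx^2 + dy^2) <= a + h &
      (!d3 | abs(Z) <= half_exp + h)
    cand <- which(near_side & !as.vector(fixed))
    if (!length(cand)) next
    cdx <- dx[cand]; cdy <- dy[cand]; cz <- Z[cand]
    th <- matrix(1, length(cand), 6)
    bv <- matrix(0, length(cand), 6)
    side_ok <- !d3 | abs(cz) <= half_exp   # lateral surface exists at this z
    # crossing of the lateral circle along +-x / +-y (no root -> NA)
    sx_ <- ifelse(cdy^2 <= a^2, sqrt(pmax(a^2 - cdy^2, 0)), NA_real_)
    sy_ <- ifelse(cdx^2 <= a^2, sqrt(pmax(a^2 - cdx^2, 0)), NA_real_)
    legs <- list(cbind((cdx - sx_) / h, 1),   # -x: first crossing
                 cbind((-cdx - sx_) / h, 2),  # +x
                 cbind((cdy - sy_) / h, 3),   # -y
                 cbind((-cdy - sy_) / h, 4))   # +y
    for (lg in legs) {
      t1 <- lg[, 1]; col <- lg[1, 2]
      ok <- is.finite(t1) & t1 > 0 & t1 <= 1 & side_ok
      th[ok, col] <- pmax(t1[ok], theta_min)
      bv[ok, col] <- ve
    }
    if (d3) {
      in_circ <- cdx^2 + cdy^2 <= a^2
      tz_top <- (cz - half_exp) / h        # approach top cap going -z
      ok <- in_circ & tz_top > 0 & tz_top <= 1
      th[ok, 5] <- pmax(tz_top[ok], theta_min); bv[ok, 5] <- ve
      tz_bot <- (-cz - half_exp) / h       # approach bottom cap going +z
      ok <- in_circ & tz_bot > 0 & tz_bot <= 1
      th[ok, 6] <- pmax(tz_bot[ok], theta_min); bv[ok, 6] <- ve
    }
    keep <- rowSums(th < 1) > 0
    cand_all <- c(cand_all, cand[keep])
    theta_full <- rbind(theta_full, th[keep, , drop = FALSE])
    bval_full <- rbind(bval_full, bv[keep, , drop = FALSE])
  }
  irr <- integer(n)
  if (length(cand_all)) irr[cand_all] <- seq_along(cand_all)
  list(irr = irr,
       theta = if (is.null(theta_full)) matrix(1, 0, 6) else theta_full,
       bval = if (is.null(bval_full)) matrix(0, 0, 6) else bval_full)
}

#' Solve the electrode conduction problem
#'
#' Computes the electric potential and field magnitude on a regular grid for
#' a paired-needle configuration by red-black SOR on the finite-difference
#' conduction equation. Heterogeneous conductivity uses harmonic-mean face
#' conductances. The solution is linear in the applied voltage.
#'
#' @param domain a [tissue_domain()].
#' @param electrodes an [electrode_pair()]; must fit inside the box.
#' @param outer outer-boundary condition: `"neumann"` (zero flux, the
#'   default, an insulated box) or `"dirichlet"`, in which case
#'   `boundary_potential` pins the outer layer.
#' @param boundary_potential for `outer = "dirichlet"`: a constant, or a
#'   function of the coordinate matrix (columns x, y\[, z\], mm) returning
#'   potentials in V. Used e.g. to impose an open-domain far field.
#' @param tol convergence tolerance: worst stencil defect in volts relative
#'   to the applied voltage span.
#' @param max_iter sweep cap; non-convergence is an error carrying the
#'   residual.
#' @return A `field_solution`: list with `potential` (V), `e_magnitude`
#'   (V/cm, central differences of the potential), `axes` (mm), `grid_step`,
#'   `residual`, `iterations`, plus the inputs.
#' @export
#' @examples
#' dom <- tissue_domain(c(24, 24), grid_step = 0.2,
#'                      electrodes = electrode_pair(applied_voltage = 100))
#' sol <- solve_field(dom, electrode_pair(applied_voltage = 100))
#' max(sol$e_magnitude)
solve_field <- function(domain, electrodes, outer = c("neumann", "dirichlet"),
                        boundary_potential = 0, tol = 1e-6, max_iter = 50000L) {
  outer <- match.arg(outer)
  stopifnot(inherits(domain, "tissue_domain"), inherits(electrodes, "electrode_pair"))
  if (electrodes$spacing + electrodes$diameter > domain$bounding_box[1])
    stop("electrodes do not fit inside the bounding box", call. = FALSE)
  axes <- grid_axes(domain)
  dims <- vapply(axes, length, 1L)
  dd <- electrode_dirichlet(electrodes, axes)
  phi <- dd$phi
  fixed <- dd$fixed

  if (outer == "dirichlet") {
    bnd <- array(FALSE, dim = dims)
    for (a in seq_along(dims)) {
      idx <- slice.index(bnd, a)
      bnd[idx == 1L | idx == dims[a]] <- TRUE
    }
    bnd <- bnd & !fixed
    if (is.function(boundary_potential)) {
      w <- which(bnd, arr.ind = TRUE)
      coords <- vapply(seq_along(axes), function(a) axes[[a]][w[, a]],
                       numeric(nrow(w)))
      phi[bnd] <- boundary_potential(coords)
    } else phi[bnd] <- boundary_potential
    fixed <- fixed | bnd
  }

  sigma <- build_sigma(domain, axes)
  cut <- electrode_cut_cells(electrodes, axes, fixed)
  res <- .sor_solve(as.numeric(phi), as.integer(dims),
                    as.numeric(sigma), as.logical(fixed),
                    cut$irr, cut$theta, cut$bval,
                    tol, as.integer(max_iter),
                    2 / (1 + sin(pi / max(dims))))
  if (!res$converged)
    stop(sprintf("field solve did not converge: residual %.3g after %d sweeps",
                 res$residual, res$iterations), call. = FALSE)
  pot <- array(res$phi, dim = dims)
  structure(list(potential = pot,
                 e_magnitude = e_magnitude_from_potential(pot, domain$grid_step),
                 axes = axes, grid_step = domain$grid_step,
                 residual = res$residual, iterations = res$iterations,
                 domain = domain, electrodes = electrodes),
            class = "field_solution")
}

## |E| in V/cm from a potential array in V on a grid in mm.
## Central differences inside, one-sided at the box faces.
e_magnitude_from_potential <- function(phi, h) {
  dims <- dim(phi)
  nd <- length(dims)
  shift <- function(a, by) {
    idx <- pmin(pmax(seq_len(dims[a]) + by, 1L), dims[a])
    if (nd == 2L) {
      if (a == 1L) phi[idx, , drop = FALSE] else phi[, idx, drop = FALSE]
    } else {
      if (a == 1L) phi[idx, , , drop = FALSE]
      else if (a == 2L) phi[, idx, , drop = FALSE]
      else phi[, , idx, drop = FALSE]
    }
  }
  grad2 <- 0
  for (a in seq_len(nd)) {
    n <- dims[a]
    span <- (pmin(seq_len(n) + 1L, n) - pmax(seq_len(n) - 1L, 1L)) * h
    g <- sweep(shift(a, 1L) - shift(a, -1L), a, span, "/")
    grad2 <- grad2 + g^2
  }
  sqrt(grad2) * 10  # V/mm -> V/cm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form field of two parallel charged wires
#'
#' Exact open-domain solution for two infinite cylindrical conductors held
#' at +V/2 and -V/2, via the equivalent line charges of the two-cylinder
#' capacitor. Serves as an independent oracle for the 2-D numerical solve.
#'
#' @param x,y evaluation coordinates, mm, origin at the pair midpoint,
#'   conductors on the x axis.
#' @param spacing center-to-center spacing, mm.
#' @param diameter conductor diameter, mm.
#' @param voltage total potential difference, V.
#' @return List with `phi` (V), `ex`, `ey` and `e_magnitude` (V/cm), shaped
#'   like `x`.
#' @export
two_wire_field <- function(x, y, spacing = 4, diameter = 0.4, voltage = 1) {
  a <- diameter / 2
  p <- sqrt((spacing / 2)^2 - a^2)      # line-charge abscissa
  K <- (voltage / 2) / acosh(spacing / diameter)
  rp2 <- (x - p)^2 + y^2
  rm2 <- (x + p)^2 + y^2
  phi <- K * 0.5 * (log(rm2) - log(rp2))
  ex <- K * ((x - p) / rp2 - (x + p) / rm2)
  ey <- K * (y / rp2 - y / rm2)
  list(phi = phi, ex = ex * 10, ey = ey * 10,
       e_magnitude = sqrt(ex^2 + ey^2) * 10)
}
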