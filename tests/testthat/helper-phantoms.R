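# Shared fixtures: phantoms (and derived geometry) are generated in code and
# cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# near-steady waveform with a unique maximum at the given frame
steady_wave <- function(n, peak = 2) {
  w <- rep(1 - 1e-9, n)
  w[peak] <- 1
  w
}

small_straight <- function() cached("small_straight", {
  generate_phantom(phantom_spec(geometry = "straight", segment_length = 60,
                                spacing = 2.5, n_timeframes = 10))
})

small_utube <- function() cached("small_utube", {
  generate_phantom(phantom_spec(geometry = "u_tube", n_timeframes = 15))
})

utube_geo <- function() cached("utube_geo", {
  ph <- small_utube()
  sp <- ph$ds$spacing
  cl <- extract_centerline(ph$lumen_mask, sp,
                           orient_point = ph$truth$centerline_points[1, ])
  cl <- place_landmarks(cl, ph$truth$landmark_fractions)
  planes <- build_planes(cl, ph$lumen_mask, sp)
  mesh <- extract_wall_mesh(ph$lumen_mask, sp, cl)
  atlas <- build_region_atlas(mesh, cl)
  list(ph = ph, cl = cl, planes = planes, mesh = mesh, atlas = atlas)
})

# independent enumeration oracles for the exact tests --------------------

oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  wp <- sum(rk[d > 0]); wm <- sum(rk[d < 0]); S <- sum(rk)
  lo <- min(wp, wm)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wps <- as.vector(signs %*% rk)
  min(1, (sum(wps <= lo + 1e-9) + sum(wps >= S - lo - 1e-9)) / 2^n)
}

oracle_mann_whitney_p <- function(a, b) {
  nA <- length(a); N <- nA + length(b)
  rk <- rank(c(a, b))
  RA <- sum(rk[seq_len(nA)])
  UA <- RA - nA * (nA + 1) / 2
  U <- min(UA, nA * (N - nA) - UA)
  hi <- nA * (N - nA) - U
  cmb <- utils::combn(N, nA)
  us <- apply(cmb, 2, function(ix) sum(rk[ix])) - nA * (nA + 1) / 2
  min(1, (sum(us <= U + 1e-9) + sum(us >= hi - 1e-9)) / ncol(cmb))
}
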