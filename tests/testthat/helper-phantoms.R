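# reduced orbital FOV used by the fast unit tests (the full 96 x 96 x 64 mm
# grid is exercised in the acceptance tests)
small_cfg <- function(...) {
  cohort_config(eye_offset_mm = 21, fov_mm = c(80, 64, 48), ...)
}
small_grid <- function() grid_config(c(80, 64, 48))

render_subject <- function(cfg, id, group = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- sample_phantom_spec(cfg, subject_id = id, group = group)
  v <- render_phantom(sp, small_grid())
  list(id = id, scan = v$scan, labels = v$labels, group = sp$group,
       spec = sp)
}

# cache a small labelled cohort across test files (built once per run)
small_cohort <- local({
  cache <- NULL
  function(n = 6, seed = 5) {
    if (is.null(cache)) {
      cfg <- small_cfg()
      set.seed(seed)
      cache <<- lapply(seq_len(n), function(i)
        render_subject(cfg, sprintf("S%d", i)))
    }
    cache
  }
})

# 6-connectivity check by flood fill from one seed voxel
is_connected <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(TRUE)
  d <- dim(mask)
  visited <- array(FALSE, d)
  visited[idx[1]] <- TRUE
  shift1 <- function(a, ax, by) {
    out <- array(FALSE, d)
    n <- d[ax]
    src <- lapply(d, seq_len); dst <- lapply(d, seq_len)
    if (by == 1) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    out <- do.call(`[<-`, c(list(out), dst,
                            list(do.call(`[`, c(list(a), src)))))
    out
  }
  repeat {
    grown <- visited
    for (ax in 1:3) for (s in c(-1, 1))
      grown <- grown | shift1(visited, ax, s)
    grown <- grown & mask
    if (sum(grown) == sum(visited)) break
    visited <- grown
  }
  sum(visited) == length(idx)
}

# random rotation matrix from uniform angles (degrees)
random_rotation <- function(max_deg = 25) {
  oculometry:::rotation_matrix(runif(3, -max_deg, max_deg))
}
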