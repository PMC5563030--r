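# Independent discrete Bloch recursion, written without reference to the
# package's closed forms or its own recursion implementation: iterate
# inversion -> TI recovery -> N x (alpha pulse, TR recovery) -> free
# recovery until the pre-readout magnetization converges.
ref_bloch <- function(tr, alpha_deg, ti, rr, n, t1, m0 = 1, beta = 1,
                      invert = TRUE) {
  a <- alpha_deg * pi / 180
  relax <- function(mz, t) 1 - (1 - mz) * exp(-t / t1)
  mz <- 0
  prev <- Inf
  for (k in 1:20000) {
    if (invert) mz <- -beta * mz
    mz <- relax(mz, ti)
    pre <- mz
    for (i in seq_len(n)) mz <- relax(mz * cos(a), tr)
    mz <- relax(mz, rr - ti - n * tr)
    if (abs(pre - prev) < 1e-14) return(m0 * pre)
    prev <- pre
  }
  stop("reference recursion did not converge")
}

# protocols used across the tests
accuracy_protocol <- function()
  seq_params(tr_ms = 5, flip_deg = 15, ti_ms = 300, rr_ms = 900,
             n_views = 33)
precision_protocol <- function(rr = 950)
  seq_params(tr_ms = 5, flip_deg = 15, ti_ms = 300, rr_ms = rr,
             n_views = 33)
swine_protocol <- function()
  seq_params(tr_ms = 3.9, flip_deg = 15, ti_ms = 300, rr_ms = 1000,
             n_views = 37)

random_valid_protocol <- function() {
  tr <- runif(1, 2, 8)
  n <- sample(1:60, 1)
  ti <- runif(1, 80, 400)
  rr <- ti + n * tr + runif(1, 50, 1200)
  seq_params(tr_ms = tr, flip_deg = runif(1, 5, 40), ti_ms = ti,
             rr_ms = rr, n_views = n,
             inversion_factor = runif(1, 0.85, 1))
}
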