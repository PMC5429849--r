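# Programmatic fixtures shared across test files.

# Binary disc image: background `bg`, disc of value `fg` and radius `r`
# centred at (cx, cy); returns list(image, mask).
disc_image <- function(n = 120, cx = 60, cy = 60, r = 20, fg = 60,
                       bg = 100) {
  inside <- outer(0:(n - 1), 0:(n - 1),
                  function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
  img <- matrix(bg, n, n)
  img[inside] <- fg
  list(image = img, mask = matrix(as.integer(inside), n, n))
}

# Random small cost matrix for oracle-equivalence trials.
random_costs <- function(R, L, max_cost = 20) {
  matrix(sample(0:max_cost, R * L, replace = TRUE), R, L)
}
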