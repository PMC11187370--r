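# small in-code fixtures shared across tests

collision_csv <- function(path, rows) {
  writeLines(c("id,date,easting,northing,severity,n_casualties", rows), path)
  path
}

three_collisions <- function(path = tempfile(fileext = ".csv")) {
  collision_csv(path, c(
    "c1,2015-03-01,1000.5,2000.25,slight,1",
    "c2,2015-03-02,1010,2010,Serious,2",
    "c3,2016-01-15,1020,1990,fatal,1"
  ))
}

# two horizontal streets 100 m apart plus one vertical street
tiny_network <- function() {
  net <- tibble::tibble(
    id = c("segA", "segB", "segC"),
    vertices = list(cbind(c(0, 100), c(0, 0)),
                    cbind(c(0, 100), c(100, 100)),
                    cbind(c(200, 200), c(0, 100))),
    limit_pre = c(30, 30, 20),
    limit_post = c(20, 30, 20),
    street_class = c("local", "main", "local")
  )
  calmstreets:::validate_network(net)
}

rect_ring <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
}

tiny_zones <- function() {
  z <- tibble::tibble(
    id = c("implA", "ctrlA"),
    rings = list(list(rect_ring(-10, -10, 110, 110)),
                 list(rect_ring(190, -10, 310, 110))),
    role = c("implementation", "control"),
    pair_id = c("p1", "p1"),
    intervention_date = as.Date(c("2016-08-01", NA))
  )
  calmstreets:::validate_zones(z)
}

# independent exact-Poisson CI oracle: invert the Poisson CDF by
# root-finding on the mean, for integer counts
poisson_ci_oracle <- function(n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (n == 0) 0 else
    uniroot(function(mu) 1 - ppois(n - 1, mu) - a, c(1e-8, n * 10 + 20),
            tol = 1e-10)$root
  hi <- uniroot(function(mu) ppois(n, mu) - a, c(1e-8, n * 10 + 50),
                tol = 1e-10)$root
  c(lo = lo, hi = hi)
}
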