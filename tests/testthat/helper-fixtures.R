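# Shared fixtures: exams are always built in code, never stored.

the_grid <- pinnacle_grid()

# exam with a single constant threshold everywhere
const_exam <- function(value, patient = "P1", eye = "right") {
  mp_exam(patient, eye, the_grid$points, rep(value, 24))
}

# exam with random integer thresholds on the device range
random_exam <- function(seed, lo = 10, hi = 32) {
  set.seed(seed)
  mp_exam(sprintf("R%03d", seed), "right", the_grid$points,
          sample(lo:hi, 24, replace = TRUE))
}

# exam CSV text for one complete eye
exam_csv_lines <- function(patient = "P1", eye = "right",
                           thresholds = rep(20, 24)) {
  pts <- the_grid$points
  c("patient_id,eye,x_deg,y_deg,threshold_db",
    sprintf("%s,%s,%g,%g,%g", patient, eye, pts$x, pts$y, thresholds))
}

# independent dense TPS solve (oracle for fit_tps/predict): builds the
# bordered (n+3) x (n+3) system explicitly and evaluates by direct summation
tps_oracle <- function(pos, val, query, lambda = 0) {
  n <- nrow(pos)
  phi <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- phi(sqrt(sum((pos[i, ] - pos[j, ])^2)))
  P <- cbind(1, pos)
  A <- rbind(cbind(K + diag(lambda, n), P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(val, 0, 0, 0))
  w <- sol[1:n]; a <- sol[n + 1:3]
  apply(query, 1, function(q) {
    a[1] + a[2] * q[1] + a[3] * q[2] +
      sum(w * phi(sqrt((pos[, 1] - q[1])^2 + (pos[, 2] - q[2])^2)))
  })
}
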