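# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately written differently from the package code
# paths they check.

# Spherical law of cosines distance (vs the package's haversine).
oracle_dist_m <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371000 * acos(pmin(1, pmax(-1, d)))
}

# Brute-force sequential clustering with an all-pairs distance matrix:
# each report joins the nearest existing cluster centre within `radius`
# (earliest cluster on ties), else starts a new cluster.  Returns cluster
# centres (first-report coordinates) and counts; fences are the clusters
# with count >= min_reports.
oracle_cluster <- function(lat, lon, radius, min_reports = 2) {
  centers <- data.frame(lat = numeric(0), lon = numeric(0),
                        count = integer(0))
  for (i in seq_along(lat)) {
    if (nrow(centers) > 0) {
      d <- oracle_dist_m(centers$lat, centers$lon, lat[i], lon[i])
      ok <- which(d <= radius)
    } else ok <- integer(0)
    if (length(ok) > 0) {
      j <- ok[which.min(d[ok])]
      centers$count[j] <- centers$count[j] + 1L
    } else {
      centers <- rbind(centers, data.frame(lat = lat[i], lon = lon[i],
                                           count = 1L))
    }
  }
  centers[centers$count >= min_reports, , drop = FALSE]
}

# Exhaustive relapse scan: TRUE iff every one of the `win` counts ending
# at position `end` exceeds `gt`.
oracle_relapse <- function(counts, end, win = 2, gt = 1) {
  if (end < win) {
    counts <- c(rep(0, win - end), counts[seq_len(end)])
  } else {
    counts <- counts[(end - win + 1):end]
  }
  all(counts > gt)
}

# Clopper-Pearson limits by bisection on the binomial tail.
oracle_cp <- function(k, n, alpha = 0.05, tol = 1e-9) {
  bisect <- function(f, lo, hi) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else
    bisect(function(p) pbinom(k - 1, n, p, lower.tail = FALSE) < alpha / 2,
           0, k / n)
  upper <- if (k == n) 1 else
    bisect(function(p) pbinom(k, n, p) >= alpha / 2, k / n, 1)
  c(lower, upper)
}

# Margin formula for the 2x2 Pearson statistic.
oracle_chisq <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# --- fixture builders -------------------------------------------------

ts_utc <- function(s) as.POSIXct(s, tz = "UTC")

HOME <- c(lat = 52.6300, lon = 1.2970)
WORK <- c(lat = 52.6410, lon = 1.3090)

# Displace a point by approximately `m` meters northwards.
north_of <- function(pt, m) c(lat = pt[["lat"]] + m / 111320,
                              lon = pt[["lon"]])

# Engine state with one established fence at HOME (two reports at 10:00
# and 10:20 on the first training day) and quit date a week later.
fenced_state <- function(config = engine_config(),
                         quit_date = as.Date("2021-01-11"), seed = 7) {
  st <- engine_new(config, quit_date = quit_date, seed = seed)
  st <- ingest_smoking_report(
    st, smoking_report(ts_utc("2021-01-04 10:00:00"), HOME[["lat"]],
                       HOME[["lon"]], situation = "home"), config)
  ingest_smoking_report(
    st, smoking_report(ts_utc("2021-01-04 10:20:00"), HOME[["lat"]],
                       HOME[["lon"]], situation = "home"), config)
}

# Feed a sequence of in-fence fixes at the given offsets (seconds) from
# `start`, collecting all decisions.
run_fixes <- function(state, config, start, offsets, at = HOME) {
  decisions <- list()
  for (o in offsets) {
    out <- ingest_location_fix(
      state, location_fix(start + o, at[["lat"]], at[["lon"]]), config)
    state <- out$state
    decisions <- c(decisions, out$decisions)
  }
  list(state = state, decisions = decisions)
}

tiny_participants <- function() {
  # counts matching the published outcome table:
  # app 104: 12 validated prolonged, 16 validated pp7, 28 self pp7, 20 pp7@6w
  # usual 105: 3, 5, 20, 21
  build_arm <- function(n, k_prol, k_pp7v, k_pp7s, k_6w, arm) {
    cot <- rep(NA_real_, n)
    sr_prol <- rep(FALSE, n); sr_pp7 <- rep(FALSE, n)
    sr_prol[seq_len(k_prol)] <- TRUE
    sr_pp7[seq_len(k_pp7s)] <- TRUE
    cot[seq_len(k_pp7v)] <- 3           # validated subset returned saliva
    sr_6w <- rep(FALSE, n); sr_6w[seq_len(k_6w)] <- TRUE
    data.frame(arm = arm, withdrawn = FALSE,
               responded_6m = TRUE, responded_6w = TRUE,
               self_report_prolonged = sr_prol,
               self_report_7day_6m = sr_pp7,
               self_report_7day_6w = sr_6w,
               cotinine = cot, anabasine = NA_real_, nrt_use = FALSE,
               stringsAsFactors = FALSE)
  }
  rbind(build_arm(104, 12, 16, 28, 20, "app"),
        build_arm(105, 3, 5, 20, 21, "usual_care"))
}
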