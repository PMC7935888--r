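test_that("expression generator honors class structure and determinism", {
  tp <- seq(0, 21, by = 3)

  # all arrhythmic, no noise: every row constant at its baseline
  sim <- simulate_expression(10, tp, c(DAY = 0, NIGHT = 0, ARRHYTHMIC = 1),
                             noise_sd = 0, seed = 3)
  expect_true(all(sim$truth$class == "ARRHYTHMIC"))
  expect_true(all(sim$truth$amplitude == 0))
  expect_equal(apply(sim$matrix, 1, function(r) diff(range(r))),
               setNames(rep(0, 10), rownames(sim$matrix)))
  expect_equal(unname(sim$matrix[, 1]), sim$truth$baseline)

  # single day gene peaks at its acrophase
  sim1 <- simulate_expression(1, tp, c(DAY = 1, NIGHT = 0, ARRHYTHMIC = 0),
                              amplitude_range = c(0.5, 0.5), noise_sd = 0,
                              acrophase_grid = 6, seed = 8)
  peak_t <- tp[which.max(sim1$matrix[1, ])]
  expect_equal(peak_t, sim1$truth$acrophase_hours)

  # acrophase class bounds hold for every generated gene
  simb <- simulate_expression(400, tp, seed = 5)
  day <- simb$truth$class == "DAY"
  night <- simb$truth$class == "NIGHT"
  expect_true(all(simb$truth$acrophase_hours[day] >= 0 &
                    simb$truth$acrophase_hours[day] < 12))
  expect_true(all(simb$truth$acrophase_hours[night] >= 12 &
                    simb$truth$acrophase_hours[night] < 24))

  # identical seed => identical output
  again <- simulate_expression(400, tp, seed = 5)
  expect_identical(simb$matrix, again$matrix)
  expect_identical(simb$truth, again$truth)

  # validation
  expect_error(simulate_expression(5, tp, c(DAY = .5, NIGHT = .4,
                                            ARRHYTHMIC = .4)), "simplex")
  expect_error(simulate_expression(5, numeric(0)), "non-empty")
  expect_error(simulate_expression(5, c(0, 3, 3, 9)), "increasing")
})

test_that("realized class counts match a binomial counting oracle", {
  fr <- c(DAY = 0.645, NIGHT = 0.355 * 57 / 78, ARRHYTHMIC = 0)
  fr["ARRHYTHMIC"] <- 1 - sum(fr)
  sim <- simulate_expression(1000, class_fractions = fr, seed = 1)
  counts <- table(factor(sim$truth$class, levels = names(fr)))
  for (cl in names(fr)) {
    expect_true(within_binomial_3sigma(counts[[cl]] / 1000, fr[[cl]], 1000),
                info = cl)
  }
})

test_that("promoter generator plants exactly what it claims under masking", {
  truth1 <- data.frame(gene_id = "g1", class = "DAY")
  fixed <- data.frame(gene_id = "g1", motif = "CACGTG",
                      distance_bp = c(400, 900, 1500))
  sim <- simulate_promoters(truth1, fixed_planted = fixed, seed = 2)
  prom <- extract_promoters(sim$genome, sim$annotation)
  hits <- scan_eboxes(prom)
  expect_equal(sort(hits$distance_bp), c(400, 900, 1500))
  expect_true(all(hits$category == "CANONICAL"))

  # zero class means + masking: no hits anywhere
  truth0 <- data.frame(gene_id = sprintf("g%d", 1:6),
                       class = rep(c("DAY", "NIGHT", "ARRHYTHMIC"), 2))
  zero <- list(DAY = c(canonical = 0, noncanonical = 0),
               NIGHT = c(canonical = 0, noncanonical = 0),
               ARRHYTHMIC = c(canonical = 0, noncanonical = 0))
  sim0 <- simulate_promoters(truth0, class_ebox_means = zero, seed = 4)
  hits0 <- scan_eboxes(extract_promoters(sim0$genome, sim0$annotation))
  expect_equal(nrow(hits0), 0)

  # masking on: every planted motif recoverable, count and position equality
  truthN <- data.frame(gene_id = sprintf("g%02d", 1:30),
                       class = rep(c("DAY", "NIGHT", "ARRHYTHMIC"), 10))
  simN <- simulate_promoters(truthN, seed = 11)
  hitsN <- scan_eboxes(extract_promoters(simN$genome, simN$annotation))
  got <- hitsN[order(hitsN$gene_id, hitsN$distance_bp),
               c("gene_id", "motif", "distance_bp")]
  want <- simN$planted[order(simN$planted$gene_id, simN$planted$distance_bp),
                       c("gene_id", "motif", "distance_bp")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)

  # determinism: byte-identical FASTA/GFF3 on re-run
  simN2 <- simulate_promoters(truthN, seed = 11)
  d <- tempfile(); dir.create(d)
  write_promoter_files(simN, file.path(d, "a.fa"), file.path(d, "a.gff3"))
  write_promoter_files(simN2, file.path(d, "b.fa"), file.path(d, "b.gff3"))
  expect_identical(readLines(file.path(d, "a.fa")),
                   readLines(file.path(d, "b.fa")))
  expect_identical(readLines(file.path(d, "a.gff3")),
                   readLines(file.path(d, "b.gff3")))
})

test_that("spontaneous canonical E-box rate matches the closed-form expectation", {
  # unmasked, nothing planted: E[CACGTG count in 3 kb] = 2995 / 4^6
  truth <- data.frame(gene_id = sprintf("g%03d", 1:1000),
                      class = rep("ARRHYTHMIC", 1000))
  zero <- list(ARRHYTHMIC = c(canonical = 0, noncanonical = 0))
  sim <- simulate_promoters(truth, class_ebox_means = zero,
                            mask_background = FALSE, seed = 9)
  hits <- scan_eboxes(extract_promoters(sim$genome, sim$annotation))
  mean_canonical <- sum(hits$category == "CANONICAL") / 1000
  expected <- 2995 / 4^6
  # counts are approximately Poisson(expected); 3 sigma Monte-Carlo band
  expect_lt(abs(mean_canonical - expected), 3 * sqrt(expected / 1000))
})

test_that("behavior generator entrains under LD and drifts under DD", {
  # LD, noiseless, acrophase 18: argmax of each 24 h block at hour 18
  ld <- simulate_behavior(3, "LD", acrophase_hours = 18, n_groups = 1,
                          noise_sd = 0)
  for (day in 0:2) {
    blk <- ld[ld$time_h >= day * 24 & ld$time_h < (day + 1) * 24, ]
    expect_equal(blk$time_h[which.max(blk$value)] %% 24, 18)
  }

  # DD, period 23: peak advances 1 h per day (hourly sampling resolves it)
  dd <- simulate_behavior(3, "DD", acrophase_hours = 18, period_hours = 23,
                          n_groups = 1, noise_sd = 0, sampling_interval = 1)
  peaks <- vapply(0:2, function(day) {
    blk <- dd[dd$time_h >= day * 24 & dd$time_h < (day + 1) * 24, ]
    blk$time_h[which.max(blk$value)] %% 24
  }, numeric(1))
  expect_equal(diff(peaks), c(-1, -1))

  # LD forces period 24 even when another period is requested
  ld2 <- simulate_behavior(2, "LD", acrophase_hours = 6, period_hours = 30,
                           n_groups = 1, noise_sd = 0)
  expect_equal(ld2$value[ld2$time_h == 6], ld2$value[ld2$time_h == 30])

  # seeded determinism
  a <- simulate_behavior(2, "DD", 18, 23, noise_sd = 0.5, seed = 42)
  b <- simulate_behavior(2, "DD", 18, 23, noise_sd = 0.5, seed = 42)
  expect_identical(a, b)
})
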