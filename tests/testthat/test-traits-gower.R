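test_that("Gower matches the defining formula on mixed toy examples", {
  # quantitative difference scaled by the table range + binary mismatch;
  # a third species widens the mass range to 10
  tt <- traitTable(
    data.frame(mass = c(5, 10, 0), foss = c("yes", "no", "yes"),
               row.names = c("s1", "s2", "s3")),
    c(mass = "quantitative", foss = "binary"))
  d <- gowerMatrix(tt)
  expect_equal(d["s1", "s2"], (0.5 + 1) / 2)
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(d, t(d))

  # identical trait vectors -> 0 (third species keeps the traits informative)
  t2 <- traitTable(data.frame(a = c(1, 1, 4), b = c("x", "x", "y"),
                              row.names = c("u", "v", "w")),
                   c(a = "quantitative", b = "categorical"))
  expect_equal(gowerMatrix(t2)["u", "v"], 0)
})

test_that("Gower agrees with brute force and cluster::daisy on random tables", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 8
    df <- data.frame(
      q1 = rnorm(n), q2 = runif(n, 0, 100), q3 = rexp(n),
      o1 = sample(1:5, n, TRUE),
      c1 = sample(c("a", "b", "c"), n, TRUE),
      b1 = sample(c("y", "n"), n, TRUE),
      row.names = paste0("sp", 1:n), stringsAsFactors = FALSE)
    # sprinkle missing values (keeping every pair jointly observed somewhere)
    df$q2[sample(n, 2)] <- NA
    df$c1[sample(n, 1)] <- NA
    types <- c(q1 = "quantitative", q2 = "quantitative", q3 = "quantitative",
               o1 = "ordinal", c1 = "categorical", b1 = "binary")
    tt <- traitTable(df, types)
    d <- gowerMatrix(tt)
    expect_equal(d, gowerBrute(df, types), tolerance = 1e-12)
  }

  skip_if_not_installed("cluster")
  # cross-check against daisy on a fully quantitative + categorical table
  set.seed(12)
  df <- data.frame(q1 = rnorm(10), q2 = runif(10),
                   c1 = factor(sample(letters[1:3], 10, TRUE)),
                   row.names = paste0("sp", 1:10))
  tt <- traitTable(df, c(q1 = "quantitative", q2 = "quantitative",
                         c1 = "categorical"))
  dMine <- gowerMatrix(tt)
  dDaisy <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(dMine, dDaisy[rownames(dMine), colnames(dMine)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Gower invariances: affine rescaling, constant traits, all-distinct categories", {
  set.seed(21)
  df <- data.frame(q1 = rnorm(6), q2 = rnorm(6),
                   c1 = sample(c("a", "b"), 6, TRUE),
                   row.names = paste0("sp", 1:6), stringsAsFactors = FALSE)
  types <- c(q1 = "quantitative", q2 = "quantitative", c1 = "categorical")
  base <- gowerMatrix(traitTable(df, types))

  # affine rescaling of one quantitative trait cancels in the range scaling
  df2 <- df; df2$q1 <- 3.7 * df$q1 - 11
  expect_equal(gowerMatrix(traitTable(df2, types)), base, tolerance = 1e-12)

  # adding a constant trait leaves the matrix unchanged (with a warning)
  df3 <- cbind(df, k = rep(1, 6))
  expect_warning(
    d3 <- gowerMatrix(traitTable(df3, c(types, k = "quantitative"))),
    "constant")
  expect_equal(d3, base, tolerance = 1e-12)

  # all-categorical, pairwise distinct on every trait -> all off-diagonals 1
  df4 <- data.frame(c1 = c("a", "b", "c"), c2 = c("x", "y", "z"),
                    row.names = c("u", "v", "w"), stringsAsFactors = FALSE)
  d4 <- gowerMatrix(traitTable(df4, c(c1 = "categorical", c2 = "categorical")))
  expect_true(all(d4[upper.tri(d4)] == 1))
})

test_that("missing overlap and ordinal conventions are handled explicitly", {
  df <- data.frame(q1 = c(1, NA, 3), q2 = c(NA, 2, 4),
                   row.names = c("u", "v", "w"))
  types <- c(q1 = "quantitative", q2 = "quantitative")
  expect_error(gowerMatrix(traitTable(df, types)), "u / v")

  # ordinal-as-mismatch option behaves like a categorical comparison
  df2 <- data.frame(o1 = c(1L, 2L, 5L), row.names = c("u", "v", "w"))
  tto <- traitTable(df2, c(o1 = "ordinal"))
  dRank <- gowerMatrix(tto)
  dMis <- gowerMatrix(tto, ordinal = "mismatch")
  expect_equal(dRank["u", "v"], 0.25)
  expect_equal(dMis["u", "v"], 1)
})

test_that("log transformation is natural-log and validates positivity", {
  tt <- traitTable(data.frame(range = c(1, exp(1), exp(2)),
                              row.names = c("u", "v", "w")),
                   c(range = "quantitative"))
  lt <- logTransformColumns(tt, "range")
  expect_equal(unname(lt@data$range), c(0, 1, 2))
  bad <- traitTable(data.frame(range = c(0, 1), row.names = c("u", "v")),
                    c(range = "quantitative"))
  expect_error(logTransformColumns(bad, "range"), "u")
})

test_that("trait CSV + schema round-trip through readTraitTable", {
  dir <- withr::local_tempdir()
  df <- data.frame(species = c("u", "v"), mass = c(1, 2),
                   diet = c("herb", "omni"))
  write.csv(df, file.path(dir, "traits.csv"), row.names = FALSE)
  write.csv(data.frame(trait = c("mass", "diet"),
                       type = c("quantitative", "categorical")),
            file.path(dir, "schema.csv"), row.names = FALSE)
  tt <- readTraitTable(file.path(dir, "traits.csv"),
                       file.path(dir, "schema.csv"))
  expect_setequal(speciesNames(tt), c("u", "v"))
  expect_equal(unname(traitTypes(tt)["diet"]), "categorical")

  # shipped schema for the 13 host traits parses
  schema <- read.csv(system.file("extdata", "host_trait_schema.csv",
                                 package = "hostNiche"))
  expect_equal(nrow(schema), 13)
  expect_true(all(schema$type %in%
                    c("quantitative", "ordinal", "categorical", "binary")))
})
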