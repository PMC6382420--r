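test_that("expression TSV round-trips and enforces its parse contract", {
  m <- matrix(c(1.5, 2.25, 0, 3.125, 4.75, 5.5), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  back <- read_expression(path)
  expect_equal(dim(back), c(3, 2))
  expect_equal(back, m, tolerance = 1e-6)

  # duplicate gene rows collapse to the highest-mean row
  writeLines(c("gene_id\ts1\ts2", "gX\t1\t3", "gX\t4\t6", "gY\t0\t0"), path)
  expect_message(dup <- read_expression(path), "collapsed 1 duplicated")
  expect_equal(nrow(dup), 2)
  expect_equal(unname(dup["gX", ]), c(4, 6))

  # a literal NA cell is a parse error naming the cell
  writeLines(c("gene_id\ts1\ts2", "gX\t1\tNA"), path)
  expect_error(read_expression(path), "non-numeric value 'NA'.*gX.*s2")

  # duplicate sample ids are rejected
  writeLines(c("gene_id\ts1\ts1", "gX\t1\t2"), path)
  expect_error(read_expression(path), "duplicate sample id")
})

test_that("log2_transform applies log2(v + pseudocount) and rejects negatives", {
  m <- matrix(c(0, 1, 7, 15), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  out <- log2_transform(m, pseudocount = 1)
  expect_equal(unname(out), matrix(c(0, 1, 3, 4), 2, 2))
  m[1, 1] <- -0.5
  expect_error(log2_transform(m), "negative")
})

test_that("mad_filter matches hand-computed MADs", {
  m <- rbind(g1 = c(1, 2, 3, 4, 100),   # median 3, abs devs {2,1,0,1,97} -> 1
             g2 = c(5, 5, 5, 5, 5),     # constant -> 0
             g3 = c(0, 10, 20, 30, 40)) # median 20, abs devs {20,10,0,10,20} -> 10
  colnames(m) <- paste0("s", 1:5)
  expect_equal(unname(gene_mads(m, 1)["g1"]), 1)
  expect_equal(unname(gene_mads(m, 1)["g2"]), 0)
  expect_identical(mad_filter(m, threshold = 0.5, scale_constant = 1),
                   c("g1", "g3"))
  expect_identical(mad_filter(m, threshold = 1e6), character(0))

  two <- rbind(g = c(0, 10)); colnames(two) <- c("s1", "s2")
  expect_equal(unname(gene_mads(two, 1)), 5)
  expect_identical(mad_filter(two, threshold = 2, scale_constant = 1), "g")
})

test_that("scaled MAD of standard-normal rows is close to 1", {
  set.seed(11)
  m <- matrix(rnorm(5 * 10000), 5, 10000,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10000)))
  expect_true(all(abs(gene_mads(m, 1.4826) - 1) < 0.1))
})

test_that("assign_arms applies the boundary rules and partitions the annotation", {
  ann <- data.frame(
    chrom = c("1", "1", "1", "19", "19", "7", "1"),
    start = c(100, 500, 121535000, 100, 27681800, 50, 200),
    end = c(200, 600, 121536000, 200, 27681900, 150, 300),
    gene_id = c("p1", "p2", "span1", "c19p", "c19q", "bg", "p3"))
  cen <- data.frame(chrom = c("1", "19", "7"),
                    p_end = c(121535434, 24451064, 1000),
                    q_start = c(124535434, 27681782, 2000))
  expect_message(am <- assign_arms(ann, cen), "span a centromere")
  expect_identical(am[["1p"]], c("p1", "p3", "p2"))  # ordered by start
  expect_identical(am[["19q"]], "c19q")
  expect_identical(attr(am, "dropped"), "span1")
  expect_true("span1" %in% am$background)
  total <- length(am[["1p"]]) + length(am[["19q"]]) + length(am$background)
  expect_equal(total, nrow(ann))

  expect_error(assign_arms(ann, cen[cen$chrom != "19", ]), "missing.*19")
})

test_that("batch_adjust standardizes per gene per batch with an sd guard", {
  set.seed(3)
  expr <- matrix(rnorm(40, 5), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  expr["g4", ] <- 2.5  # constant gene: sd guard
  batch <- rep(c("A", "B"), each = 5)
  labels <- rep(c("codeleted", "intact"), 5)
  d <- codel_dataset(expr, labels, batch = batch)
  adj <- batch_adjust(d)
  for (b in c("A", "B")) {
    expect_true(all(abs(rowMeans(adj$expr[, batch == b])) < 1e-10))
  }

  # a pure gene-wise shift between batches leaves identical per-batch means
  shifted <- expr
  shifted[, batch == "B"] <- shifted[, batch == "B"] + c(1, -2, 3, 0)
  adj2 <- batch_adjust(codel_dataset(shifted, labels, batch = batch))
  expect_equal(rowMeans(adj2$expr[, batch == "A"]),
               rowMeans(adj2$expr[, batch == "B"]), tolerance = 1e-10)

  # constant gene is centered but not rescaled
  expect_equal(unname(adj$expr["g4", ]), rep(0, 10))

  single <- codel_dataset(expr, labels, batch = rep("A", 10))
  expect_warning(same <- batch_adjust(single), "identity")
  expect_equal(same$expr, expr)
})

test_that("dataset construction enforces matrix and label invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  storage.mode(m) <- "double"
  expect_error(codel_dataset(m, c("codeleted", "bogus")), "invalid status")
  m2 <- m; m2[1, 1] <- NA
  expect_error(codel_dataset(m2, c("codeleted", "intact")), "non-finite")
  d <- codel_dataset(m, c(s2 = "intact", s1 = "codel"))  # named, reordered
  expect_identical(as.character(d$labels), c("codeleted", "intact"))
})
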