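test_that("query expansion covers self, synonyms and descendants", {
  g <- tiny_dag()
  exp_a <- expand_query(g, "Alpha")
  expect_true(all(c("alpha", "beta", "gamma", "delta") %in% exp_a$keys$key))
  expect_true("t:b" %in% exp_a$keys$key) # descendant CURIEs match too

  exp_b <- expand_query(g, "Beta")
  expect_true("ace inhibitor" %in% exp_b$keys$key)

  expect_warning(exp_u <- expand_query(g, "xyz"), "unresolved")
  expect_identical(exp_u$keys$key, "xyz")
})

test_that("tree_filter matches descendants, supersets exact matching", {
  g <- tiny_dag()
  tb <- tibble::tibble(
    curation_id = sprintf("s:%d", 1:4),
    disease = c("Alpha", "Delta", "Gamma;Delta", NA))
  # querying the root finds every annotated row (descendant subtypes included)
  expect_identical(tree_filter(tb, "disease", "Alpha", g)$curation_id,
                   c("s:1", "s:2", "s:3"))
  # exact string filtering is always a subset
  exact <- tb[!is.na(tb$disease) & tb$disease == "Beta", ]
  expect_true(all(exact$curation_id %in%
                    tree_filter(tb, "disease", "Beta", g)$curation_id))
  # NA never matches; row order preserved
  res <- tree_filter(tb, "disease", c("Gamma", "Delta"), g, logic = "any")
  expect_identical(res$curation_id, c("s:2", "s:3"))
  expect_error(tree_filter(tb, "ghost", "Alpha", g), "unknown attribute")
})

test_that("logic=all requires every query term to be hit", {
  g <- tiny_dag()
  tb <- tibble::tibble(disease = c("Delta", "Gamma;Delta", "Gamma"))
  res <- tree_filter(tb, "disease", c("Beta", "Gamma"), g, logic = "all")
  expect_identical(res$disease, "Gamma;Delta")
  one_token <- tibble::tibble(disease = "Delta")
  expect_identical(
    nrow(tree_filter(one_token, "disease", c("Beta", "Gamma"), g, "all")), 0L)
})

test_that("tree_filter equals a brute-force scan with the oracle expansion", {
  for (seed in 1:20) {
    g <- random_dag(25, seed = seed + 300)
    set.seed(seed)
    labels <- g$terms$label
    tb <- tibble::tibble(attr = replicate(30, paste(
      sample(labels, sample(1:3, 1)), collapse = ";")))
    tb$attr[sample(30, 5)] <- NA
    q <- sample(labels, 1)
    qid <- g$terms$id[match(q, labels)]
    pool_ids <- oracle_relatives(g, qid, "descendants", include_self = TRUE)
    i <- match(pool_ids, g$terms$id)
    keys <- tolower(c(q, pool_ids, g$terms$label[i],
                      unlist(g$terms$synonyms[i])))
    brute <- vapply(tb$attr, function(cell) {
      if (is.na(cell)) return(FALSE)
      any(tolower(strsplit(cell, ";", fixed = TRUE)[[1]]) %in% keys)
    }, logical(1))
    expect_identical(tree_filter(tb, "attr", q, g)$attr, tb$attr[brute])
  }
})

test_that("adding query terms under logic=any never shrinks the result", {
  g <- random_dag(30, seed = 77)
  set.seed(77)
  tb <- tibble::tibble(attr = sample(g$terms$label, 40, replace = TRUE))
  q1 <- tree_filter(tb, "attr", "rd node 3", g)
  q2 <- tree_filter(tb, "attr", c("rd node 3", "rd node 5"), g)
  expect_gte(nrow(q2), nrow(q1))
  expect_true(all(q1$attr %in% q2$attr))
})

test_that("multi-valued spread yields one row per token and is invertible", {
  tb <- tibble::tibble(curation_id = c("a:1", "a:2", "a:3"),
                       treatment = c("Metformin;Aspirin", "Statin", NA))
  sp <- spread_meta(tb, "treatment", "multi")
  expect_identical(nrow(sp), 4L)
  expect_identical(sp$treatment[sp$curation_id == "a:1"],
                   c("Metformin", "Aspirin"))
  expect_identical(attr(sp, "spread_on"), "treatment")
  # idempotent on already-spread input
  expect_identical(spread_meta(sp, "treatment", "multi"), sp)
  # spread tables relax curation_id uniqueness in structural validation
  dict <- data_dictionary(attribute_spec("treatment", "multi"))
  expect_identical(nrow(validate_structure(sp, dict)), 0L)

  back <- gather_meta(sp, "treatment", "multi")
  expect_identical(as.data.frame(back), as.data.frame(tb))
})

test_that("composite spread makes one column per member", {
  tb <- tibble::tibble(curation_id = c("a:1", "a:2"),
                       biomarker = c("CRP:2.3;IL6:1.1", "CRP:4.0"))
  sp <- spread_meta(tb, "biomarker", "composite")
  expect_identical(sp$biomarker_CRP, c("2.3", "4.0"))
  expect_identical(sp$biomarker_IL6, c("1.1", NA))
  back <- gather_meta(sp, "biomarker", "composite")
  expect_identical(back$biomarker, tb$biomarker)

  bad <- tibble::tibble(curation_id = "a:9", biomarker = "noseparator")
  expect_error(spread_meta(bad, "biomarker", "composite"), "a:9")
})

test_that("gather rejects non-rectangular context", {
  sp <- tibble::tibble(curation_id = c("a:1", "a:1"),
                       sex = c("M", "F"),
                       treatment = c("x", "y"))
  expect_error(gather_meta(sp, "treatment", "multi"), "non-rectangular")
})

test_that("gather(spread(t)) is the canonical identity on random fixtures", {
  set.seed(99)
  for (rep in 1:200) {
    kind <- if (rep %% 2 == 0) "multi" else "composite"
    n <- sample(1:6, 1)
    ctx <- tibble::tibble(
      curation_id = sprintf("s:%d", seq_len(n)),
      sex = sample(c("M", "F", NA), n, replace = TRUE))
    if (kind == "multi") {
      ctx$attr <- replicate(n, {
        k <- sample(0:3, 1)
        if (k == 0) NA_character_ else
          paste(sample(c("A", "B", "C", "D"), k), collapse = ";")
      })
    } else {
      ctx$attr <- replicate(n, {
        k <- sample(0:3, 1)
        if (k == 0) NA_character_ else
          paste(sample(c("crp", "il6", "tnf"), k),
                round(runif(k), 2), sep = ":", collapse = ";")
      })
    }
    back <- gather_meta(spread_meta(ctx, "attr", kind), "attr", kind)
    back <- back[match(ctx$curation_id, back$curation_id), ]
    expect_identical(back$sex, ctx$sex)
    # token sets are preserved exactly (composite member order follows
    # column order, so compare as sets)
    expect_identical(canonical_cells(back$attr, sort = TRUE),
                     canonical_cells(ctx$attr, sort = TRUE))
  }
})

test_that("one-row tables survive reshaping unchanged", {
  tb <- tibble::tibble(curation_id = "a:1", attr = "X")
  sp <- spread_meta(tb, "attr", "multi")
  expect_identical(nrow(sp), 1L)
  expect_identical(gather_meta(sp, "attr", "multi")$attr, "X")
})
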