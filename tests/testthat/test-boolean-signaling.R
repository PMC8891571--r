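# Boolean signalling network: rule parsing, dynamics, attractors and the
# receptor-input -> phenotype map.

net <- bn_load_rules()

write_rules <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("node\tclass\texpression\treference", lines), f)
  f
}

test_that("rule table loads with the published structure and validates", {
  expect_length(net$externals, 6)
  expect_length(net$internals, 29)
  expect_length(net$outputs, 4)
  expect_setequal(net$externals,
                  c("Integrin", "RTK", "E-cadherin", "Wnt", "APC", "NF1"))
  # FAK depends only on integrin engagement
  expect_equal(net$rules[["FAK"]], list(op = "var", name = "Integrin"))
  # empty table is rejected
  expect_error(bn_load_rules(write_rules(character(0))), "empty")
  # unknown node reference is rejected
  expect_error(bn_load_rules(write_rules(c("A\texternal\tExternal signal\t-",
                                           "B\tinternal\tA And Zz\t-"))),
               "unknown node")
  # an external node with a dependence expression is a cyclic definition
  expect_error(bn_load_rules(write_rules(c("A\texternal\tA\t-"))), "cyclic")
})

test_that("synchronous update follows the dependence relations", {
  st <- bn_state(net, inputs = c(Integrin = TRUE),
                 internals = setNames(rep(FALSE, 33),
                                      c(net$internals, net$outputs)))
  nxt <- bn_step(net, st)
  expect_true(nxt[["FAK"]])            # integrin engages FAK
  st2 <- bn_state(net, internals = c(Mdm2 = TRUE, p53 = TRUE))
  expect_false(bn_step(net, st2)[["p53"]])  # Mdm2 degrades p53
  # determinism: identical state in, identical state out
  expect_identical(bn_step(net, st), bn_step(net, st))
  # a fixed point maps to itself
  set.seed(4)
  att <- bn_run_to_attractor(net, bn_state(net, inputs = c(
    Integrin = TRUE, RTK = TRUE, `E-cadherin` = TRUE)))
  fp <- setNames(att$states[1, ], net$nodes)
  expect_identical(unname(bn_step(net, fp)[net$nodes]), unname(fp))
})

test_that("attractors reproduce the canonical phenotype-map entries", {
  run <- function(...) {
    st <- bn_state(net, inputs = c(...))
    bn_run_to_attractor(net, st)$phenotype$code
  }
  set.seed(11)
  # integrin + RTK + cadherin on, Wnt and both suppressors off: growth and
  # proliferation without migration
  expect_identical(run(Integrin = TRUE, RTK = TRUE, `E-cadherin` = TRUE),
                   "1100")
  # restoring NF1 in the same setting flips the cell into apoptosis
  expect_identical(run(Integrin = TRUE, RTK = TRUE, `E-cadherin` = TRUE,
                       NF1 = TRUE), "0010")
  # the fully migratory phenotype needs Wnt with cadherin loss
  expect_identical(run(Integrin = TRUE, RTK = TRUE, Wnt = TRUE), "1101")
  # loss of either survival input sets the apoptosis bit
  expect_identical(substr(run(Integrin = TRUE, RTK = FALSE), 3, 3), "1")
  expect_identical(substr(run(Integrin = FALSE, RTK = TRUE), 3, 3), "1")
})

test_that("the input-output map has three biological phenotype classes", {
  m <- bn_input_output_map(net, n_seeds = 256, seed = 5)
  expect_equal(nrow(m), 64)
  expect_setequal(unique(m$code), c("1100", "1101", "0010", "0011"))
  # apoptosis codes are one class: three biologically relevant phenotypes
  classes <- unique(sub("^001[01]$", "apoptosis", m$code))
  expect_length(classes, 3)
  expect_equal(sum(m$figure_map), 16)
  # the map is a pure function of the external bits: a different internal
  # seeding yields the same map
  m2 <- bn_input_output_map(net, n_seeds = 256, seed = 99)
  expect_identical(m$code, m2$code)
  # apoptosis whenever RTK or integrin is silent, regardless of cadherin
  off <- !m$RTK | !m$Integrin
  expect_true(all(substr(m$code[off], 3, 3) == "1"))
  # in the presence of both survival signals and absence of Wnt, cadherin
  # blocks migration
  sel <- m$RTK & m$Integrin & !m$Wnt & m[["E-cadherin"]] & !m$APC & !m$NF1
  expect_true(all(substr(m$code[sel], 4, 4) == "0"))
})

test_that("cycle attractors read out with strict AND across states", {
  toy <- bn_load_rules(write_rules(c(
    "E\texternal\tExternal signal\t-",
    "X\tinternal\tNot X\t-",
    "Osc\toutput\tX\t-",
    "Const\toutput\tE\t-")))
  st <- bn_state(toy, inputs = c(E = TRUE), internals = c(X = TRUE))
  att <- bn_run_to_attractor(toy, st)
  expect_equal(att$period, 2)
  ph <- bn_phenotype(att)
  expect_false(ph$bits[["Osc"]])   # oscillating bit resolves to off
  expect_true(ph$bits[["Const"]])  # constant bit stays on
  # non-convergence within the step budget is an explicit error
  expect_error(bn_run_to_attractor(toy, st, max_steps = 1), "no attractor")
})

test_that("robustness scan reaches exactly the four attractors", {
  rs <- bn_robustness_scan(net, n_samples = 2000, seed = 1729)
  expect_identical(rs$phenotypes, c("0010", "0011", "1100", "1101"))
  expect_equal(sum(rs$census$count), 64 * 2000)
  # a single sample reaches a single attractor
  rs1 <- bn_robustness_scan(net, inputs = c(Integrin = TRUE, RTK = TRUE,
                                            `E-cadherin` = TRUE, Wnt = FALSE,
                                            APC = FALSE, NF1 = FALSE),
                            n_samples = 1, seed = 2)
  expect_length(rs1$phenotypes, 1)
  # exhaustive enumeration of 2^29 internal states trips the guard with an
  # advisory pointing at sampling
  expect_error(bn_robustness_scan(net, exhaustive = TRUE), "sampling")
  # on a small network exhaustive enumeration works and matches sampling
  toy <- bn_load_rules(write_rules(c(
    "E\texternal\tExternal signal\t-",
    "A\tinternal\tE\t-",
    "B\tinternal\tA And Not B\t-",
    "Out\toutput\tB\t-")))
  ex <- bn_robustness_scan(toy, inputs = c(E = FALSE), exhaustive = TRUE)
  expect_equal(sum(ex$census$count), 4)  # 2^2 internal states
})

test_that("switching external inputs reconverges after only a few updates", {
  set.seed(3)
  a <- bn_run_to_attractor(net, bn_state(net, inputs = c(
    Integrin = TRUE, RTK = TRUE, `E-cadherin` = TRUE)))
  fp <- setNames(a$states[1, ], net$nodes)
  class(fp) <- c("bn_state", class(fp))
  fp[c("Integrin", "RTK", "E-cadherin", "Wnt", "APC", "NF1")] <-
    c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  b <- bn_run_to_attractor(net, fp)
  expect_lte(b$steps, 15)
  expect_identical(b$phenotype$code, "1101")
})

test_that("asynchronous sweeps settle into the same fixed point", {
  set.seed(8)
  st <- bn_state(net, inputs = c(Integrin = TRUE, RTK = TRUE,
                                 `E-cadherin` = TRUE))
  for (i in 1:40) st <- bn_step(net, st, update = "asynchronous")
  expect_identical(paste(as.integer(st[net$outputs]), collapse = ""), "1100")
})
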