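# Small fixture builders shared across test files; everything is generated in
# code, no data files.

nwk3 <- "((A:1,B:1):1,C:2);"
nwk4 <- "(((A:1,B:1):1,C:2):1,D:3);"

read_nwk_text <- function(text) {
  path <- withr::local_tempfile(fileext = ".nwk", .local_envir = parent.frame())
  writeLines(text, path)
  read_newick(path)
}

tree3 <- function() ape::read.tree(text = nwk3)
tree4 <- function() ape::read.tree(text = nwk4)

# a reproducible pair of reconstructed birth-death trees
bd_pair <- function(seed = 101, lambda = c(0.06, 0.06), mu = c(0.015, 0.015),
                    depth = c(50, 50), min_tips = 5) {
  set.seed(seed)
  multi_tree_data(list(
    simulate_crown_bd(lambda[1], mu[1], depth[1], min_tips = min_tips),
    simulate_crown_bd(lambda[2], mu[2], depth[2], min_tips = min_tips)
  ))
}
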