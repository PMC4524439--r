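# Shared small fixtures, all generated in code under fixed seeds.

smallDesign <- function(nPairs = 10, seed = 101, ...) {
  generateCohort(nPairs, seed = seed, ...)
}

smallGenes <- function(nGenes = 150, seed = 102, ...) {
  generateGeneAnnotation(nGenes, seed = seed, ...)
}

smallAnnot <- function(nProbes = 800, seed = 103, geneAnnot = NULL, ...) {
  generateProbeAnnotation(nProbes, seed = seed, geneAnnot = geneAnnot, ...)
}

# a tiny hand-built ontology:
#        root
#       /    \
#      A      B
#     / \      \
#    A1  A2     B1 (+ B1dup, a near-duplicate child of B1)
tinyUniverse <- function(nGenes = 200) {
  genes <- sprintf("g%03d", seq_len(nGenes))
  parents <- list(root = character(0),
                  A = "root", B = "root",
                  A1 = "A", A2 = "A", B1 = "B", B1dup = "B1")
  annotation <- list(root = genes,
                     A = genes[1:80], B = genes[101:180],
                     A1 = genes[1:30], A2 = genes[41:70],
                     B1 = genes[101:140], B1dup = genes[103:142])
  termUniverse(parents, annotation)
}
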