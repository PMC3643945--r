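#include <Rcpp.h>
using namespace Rcpp;

// Tabular (recursive) kinship over a pedigree given in topological order:
// parents always precede children; father[i], mother[i] are 1-based row
// indices, 0 for founders.  Exact on looped (consanguineous) pedigrees.
// [[Rcpp::export(name = ".kinship_tabular")]]
NumericMatrix kinship_tabular(IntegerVector father, IntegerVector mother) {
  const int n = father.size();
  NumericMatrix phi(n, n);
  for (int i = 0; i < n; ++i) {
    const int f = father[i], m = mother[i];
    if (f == 0) {
      phi(i, i) = 0.5;
    } else {
      phi(i, i) = 0.5 * (1.0 + phi(f - 1, m - 1));
    }
    for (int j = 0; j < i; ++j) {
      double v;
      if (f == 0) {
        v = 0.0; // founder: unrelated to everyone ordered before it
      } else {
        v = 0.5 * (phi(f - 1, j) + phi(m - 1, j));
      }
      phi(i, j) = v;
      phi(j, i) = v;
    }
  }
  return phi;
}

// Gene dropping with Haldane recombination.  Founder rows of hap_pat/hap_mat
// hold the founder haplotypes (arbitrary integer alleles); non-founder rows
// are overwritten.  theta has length n_loci - 1 (adjacent-interval
// recombination fractions).  Uses R's RNG, so set.seed() governs the drop.
// [[Rcpp::export(name = ".gene_drop_cpp")]]
List gene_drop_cpp(IntegerVector father, IntegerVector mother,
                   IntegerMatrix hap_pat, IntegerMatrix hap_mat,
                   NumericVector theta) {
  const int n = father.size();
  const int L = hap_pat.ncol();
  if (hap_mat.ncol() != L || hap_pat.nrow() != n || hap_mat.nrow() != n)
    stop("haplotype matrix dimensions inconsistent with pedigree");
  if (theta.size() != (L > 0 ? L - 1 : 0))
    stop("theta must have length n_loci - 1");
  IntegerMatrix out_pat = clone(hap_pat);
  IntegerMatrix out_mat = clone(hap_mat);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    const int f = father[i], m = mother[i];
    if (f == 0) continue;
    // gamete from father -> paternal haplotype of child
    int strand = unif_rand() < 0.5 ? 0 : 1;
    for (int l = 0; l < L; ++l) {
      if (l > 0 && unif_rand() < theta[l - 1]) strand = 1 - strand;
      out_pat(i, l) = strand == 0 ? out_pat(f - 1, l) : out_mat(f - 1, l);
    }
    // gamete from mother -> maternal haplotype of child
    strand = unif_rand() < 0.5 ? 0 : 1;
    for (int l = 0; l < L; ++l) {
      if (l > 0 && unif_rand() < theta[l - 1]) strand = 1 - strand;
      out_mat(i, l) = strand == 0 ? out_pat(m - 1, l) : out_mat(m - 1, l);
    }
  }
  return List::create(_["pat"] = out_pat, _["mat"] = out_mat);
}
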