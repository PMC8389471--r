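#include <Rcpp.h>
using namespace Rcpp;

// Sequential checkerboard-swap Markov chain on a binary matrix. Each swap
// attempt draws two rows and two columns; when the 2x2 submatrix is a
// checkerboard ([[1,0],[0,1]] or [[0,1],[1,0]]) its diagonal is flipped,
// preserving all row and column sums. The chain records, after `burnin`
// attempts and then every `thin` attempts, the overlap statistic between
// the two focal columns (number of rows equal to 1 in both). Uses R's RNG
// so results honor set.seed().
// [[Rcpp::export(name = ".checkerboardNullOverlap")]]
IntegerVector checkerboard_null_overlap(IntegerMatrix x, int colA, int colB,
                                        int nsim, double thin, double burnin) {
    IntegerMatrix m = clone(x);
    const int nr = m.nrow();
    const int nc = m.ncol();
    if (nr < 2 || nc < 2)
        stop("matrix must have at least two rows and two columns");
    IntegerVector out(nsim);
    const int a = colA - 1, b = colB - 1;

    // count_success: advance by successful swaps (burn-in, where thorough
    // decorrelation from the observed matrix matters) or by attempts
    // (thinning between samples). A cap guards degenerate matrices with no
    // reachable checkerboard.
    auto sweep = [&](double steps, bool count_success) {
        const double max_attempts = count_success ? steps * 1e4 + 1e6 : steps;
        double done = 0;
        for (double att = 0; att < max_attempts && done < steps; att++) {
            int r1 = (int)(unif_rand() * nr);
            int r2 = (int)(unif_rand() * (nr - 1));
            if (r2 >= r1) r2++;
            int c1 = (int)(unif_rand() * nc);
            int c2 = (int)(unif_rand() * (nc - 1));
            if (c2 >= c1) c2++;
            const int v11 = m(r1, c1), v12 = m(r1, c2);
            const int v21 = m(r2, c1), v22 = m(r2, c2);
            if (v11 == v22 && v12 == v21 && v11 != v12) {
                m(r1, c1) = v12; m(r1, c2) = v11;
                m(r2, c1) = v22; m(r2, c2) = v21;
                if (count_success) done++;
            }
            if (!count_success) done++;
        }
    };

    sweep(burnin, true);
    for (int s = 0; s < nsim; s++) {
        sweep(thin, false);
        int ov = 0;
        for (int r = 0; r < nr; r++)
            if (m(r, a) == 1 && m(r, b) == 1) ov++;
        out[s] = ov;
    }
    return out;
}
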