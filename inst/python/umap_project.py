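"""2-D UMAP projection helper: matrix TSV in, coordinate TSV out.

Usage: umap_project.py IN_TSV OUT_TSV N_NEIGHBORS MIN_DIST SEED
All UMAP parameters other than n_neighbors/min_dist/random_state are left
at the library defaults.
"""
import sys

import numpy as np
import umap


def main() -> None:
    in_tsv, out_tsv, n_neighbors, min_dist, seed = sys.argv[1:6]
    x = np.loadtxt(in_tsv, delimiter="\t", ndmin=2)
    reducer = umap.UMAP(
        n_neighbors=int(n_neighbors),
        min_dist=float(min_dist),
        n_components=2,
        random_state=int(seed),
    )
    coords = reducer.fit_transform(x)
    np.savetxt(out_tsv, coords, delimiter="\t")


if __name__ == "__main__":
    main()
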