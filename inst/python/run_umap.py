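"""UMAP runner: project a CSV matrix to 2-D.

Usage: python run_umap.py IN_CSV OUT_CSV N_NEIGHBORS MIN_DIST SEED
"""
import sys

import numpy as np
import umap


def main(argv):
    in_csv, out_csv = argv[1], argv[2]
    n_neighbors = int(argv[3])
    min_dist = float(argv[4])
    seed = int(argv[5])
    X = np.loadtxt(in_csv, delimiter=",", ndmin=2)
    reducer = umap.UMAP(
        n_components=2,
        n_neighbors=n_neighbors,
        min_dist=min_dist,
        random_state=seed,
        n_jobs=1,
    )
    emb = reducer.fit_transform(X)
    np.savetxt(out_csv, emb, delimiter=",")
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
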