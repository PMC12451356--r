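"""Sparse LP solve via scipy's bundled HiGHS.

Protocol: a directory containing
  meta.json : {"n": cols, "m": rows, "nnz": triplets}
  c.bin     : float64[n]   objective
  b.bin     : float64[m]   RHS of A x <= b
  lb.bin    : float64[n]   lower bounds (-1e30 = -inf)
  ub.bin    : float64[n]   upper bounds (+1e30 = +inf)
  ai.bin    : int32[nnz]   0-based row indices
  aj.bin    : int32[nnz]   0-based col indices
  ax.bin    : float64[nnz] values
Writes x.bin (float64[n]) and result.json {"status", "message", "fun"}.
Exit code is 0 whenever a result file was written (including infeasible).
"""
import json
import os
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import linprog


def main(d):
    with open(os.path.join(d, "meta.json")) as fh:
        meta = json.load(fh)
    n, m, nnz = meta["n"], meta["m"], meta["nnz"]
    rd = lambda name, dt, k: np.fromfile(os.path.join(d, name), dtype=dt, count=k)
    c = rd("c.bin", np.float64, n)
    b = rd("b.bin", np.float64, m)
    lb = rd("lb.bin", np.float64, n)
    ub = rd("ub.bin", np.float64, n)
    ai = rd("ai.bin", np.int32, nnz)
    aj = rd("aj.bin", np.int32, nnz)
    ax = rd("ax.bin", np.float64, nnz)
    lb = np.where(lb <= -1e30, -np.inf, lb)
    ub = np.where(ub >= 1e30, np.inf, ub)
    A = sparse.coo_matrix((ax, (ai, aj)), shape=(m, n)).tocsc() if m > 0 else None
    res = linprog(
        c=c,
        A_ub=A,
        b_ub=b if m > 0 else None,
        bounds=np.column_stack([lb, ub]),
        method=meta.get("method", "highs-ipm"),
    )
    x = res.x if res.x is not None else np.zeros(n)
    np.asarray(x, dtype=np.float64).tofile(os.path.join(d, "x.bin"))
    with open(os.path.join(d, "result.json"), "w") as fh:
        json.dump(
            {
                "status": int(res.status),
                "message": str(res.message),
                "fun": float(res.fun) if res.fun is not None else None,
            },
            fh,
        )


if __name__ == "__main__":
    main(sys.argv[1])
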