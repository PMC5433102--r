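"""Solve a mixed-integer linear program with HiGHS via scipy.optimize.milp.

Usage: python milp_highs.py MODEL.json RESULT.json

The model is a JSON object with fields ncol, nrow, obj, lb, ub,
integrality (0/1 per column), ai/aj/av (0-based constraint triplets),
rl, ru (row bounds) and time_limit (seconds). Magnitudes >= 1e29 in any
bound are treated as infinite.
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import coo_matrix


def definite(x):
    x = np.asarray(x, dtype=float)
    x[x >= 1e29] = np.inf
    x[x <= -1e29] = -np.inf
    return x


def main():
    with open(sys.argv[1]) as fh:
        m = json.load(fh)
    ncol, nrow = int(m["ncol"]), int(m["nrow"])
    A = coo_matrix(
        (np.asarray(m["av"], dtype=float),
         (np.asarray(m["ai"], dtype=int), np.asarray(m["aj"], dtype=int))),
        shape=(nrow, ncol),
    ).tocsr()
    res = milp(
        c=np.asarray(m["obj"], dtype=float),
        constraints=LinearConstraint(A, definite(m["rl"]), definite(m["ru"])),
        integrality=np.asarray(m["integrality"], dtype=int),
        bounds=Bounds(definite(m["lb"]), definite(m["ub"])),
        options={"time_limit": float(m.get("time_limit", 600)),
                 "mip_rel_gap": 0.0},
    )
    status = {0: "optimal", 1: "feasible", 2: "infeasible",
              3: "unbounded"}.get(res.status, "unknown")
    if status == "feasible" and res.x is None:
        status = "unknown"
    out = {
        "status": status,
        "objective": None if res.fun is None else float(res.fun),
        "x": None if res.x is None else [float(v) for v in res.x],
        "bound": (None if getattr(res, "mip_dual_bound", None) is None
                  else float(res.mip_dual_bound)),
        "gap": (None if getattr(res, "mip_gap", None) is None
                else float(res.mip_gap)),
    }
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
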