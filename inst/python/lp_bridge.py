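"""Batched LP/MILP solve server.

Reads a JSON request file holding a list of problems, solves each with
scipy's HiGHS backend (scipy.optimize.milp handles both pure LPs and
MILPs), and writes a JSON response. All problems are minimisation; the
caller negates objectives for maximisation. Constraints are a single
sparse matrix A with row lower/upper bounds (use +/-1e30 for free sides).

A problem may carry an "enumerate" directive: the objective (sum of the
given binary variables) is first minimised, then every alternative
support within `slack` of the minimum is enumerated by re-solving with
integer cuts sum_{j in S} y_j <= |S|-1, which exclude each found set and
all of its supersets, so the enumeration returns exactly the minimal
feasible sets within the size budget.

Usage: python lp_bridge.py request.json response.json
"""

import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import csr_matrix

INF = 1e30

STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded", 4: "numerical"}


def as_list(v):
    return v if isinstance(v, list) else [v]


def build_matrix(spec, extra_rows=None):
    i = np.asarray(as_list(spec.get("i", [])), dtype=int)
    j = np.asarray(as_list(spec.get("j", [])), dtype=int)
    x = np.asarray(as_list(spec.get("x", [])), dtype=float)
    m = int(spec["m"])
    n = int(spec["n"])
    if extra_rows:
        for row in extra_rows:
            i = np.concatenate([i, np.full(len(row["j"]), m, dtype=int)])
            j = np.concatenate([j, np.asarray(row["j"], dtype=int)])
            x = np.concatenate([x, np.asarray(row["x"], dtype=float)])
            m += 1
    return csr_matrix((x, (i, j)), shape=(m, n)), m


def clip_inf(v):
    v = np.asarray(as_list(v), dtype=float)
    v[v > INF] = np.inf
    v[v < -INF] = -np.inf
    return v


def solve_one(c, A, row_lb, row_ub, lb, ub, integrality):
    cons = LinearConstraint(A, row_lb, row_ub)
    res = milp(
        c=c,
        constraints=cons,
        bounds=Bounds(lb, ub),
        integrality=integrality,
        options={"presolve": True},
    )
    status = STATUS.get(res.status, "numerical")
    if res.status == 0 and res.x is None:
        status = "numerical"
    return status, res


def run_problem(p):
    c = np.asarray(as_list(p["c"]), dtype=float)
    n = len(c)
    lb = clip_inf(p["lb"])
    ub = clip_inf(p["ub"])
    integrality = np.asarray(as_list(p.get("integrality", [0] * n)), dtype=int)
    row_lb = clip_inf(p.get("row_lb", []))
    row_ub = clip_inf(p.get("row_ub", []))

    enum = p.get("enumerate")
    if enum is None:
        A, _ = build_matrix(p["A"])
        status, res = solve_one(c, A, row_lb, row_ub, lb, ub, integrality)
        out = {"status": status}
        if status == "optimal":
            out["objective"] = float(res.fun)
            out["x"] = [float(v) for v in res.x]
        return out

    binary_idx = [int(k) for k in as_list(enum["binary_idx"])]
    slack = int(enum.get("slack", 0))
    max_solutions = int(enum.get("max_solutions", 10000))
    extra = []

    def resolve():
        A, _ = build_matrix(p["A"], extra)
        rl = np.concatenate([row_lb, [-np.inf] * len(extra)])
        ru = np.concatenate([row_ub, [r["ub"] for r in extra]])
        return solve_one(c, A, rl, ru, lb, ub, integrality)

    status, res = resolve()
    if status != "optimal":
        return {"status": status, "sets": []}
    kmin = int(round(res.fun))
    budget = kmin + slack
    # cap total selected binaries at the budget
    extra.append({"j": binary_idx, "x": [1.0] * len(binary_idx), "ub": float(budget)})
    sets = []
    while len(sets) < max_solutions:
        status, res = resolve()
        if status != "optimal":
            break
        sel = [j for j in binary_idx if res.x[j] > 0.5]
        sets.append(sorted(sel))
        if not sel:
            break  # empty support feasible: nothing smaller to exclude
        extra.append({"j": sel, "x": [1.0] * len(sel), "ub": float(len(sel) - 1)})
    return {"status": "optimal", "minimum": kmin, "sets": sets}


def main(argv):
    with open(argv[1]) as fh:
        req = json.load(fh)
    problems = req.get("problems", [])
    if isinstance(problems, dict):
        problems = [problems]
    solutions = [run_problem(p) for p in problems]
    with open(argv[2], "w") as fh:
        json.dump({"solutions": solutions}, fh)


if __name__ == "__main__":
    main(sys.argv)
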