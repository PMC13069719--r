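"""Batch LP solver used by the dip-statistic test oracle.

Reads a JSON file with a list of linear programs (minimise c'x subject to
A x <= / >= b, x >= 0), solves each with scipy's HiGHS backend at tight
tolerances, and writes the optimal objective values back as JSON.

Usage: python lp_solve.py problems.json values.json
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve_one(prob):
    c = np.asarray(prob["c"], dtype=float)
    A = np.asarray(prob["A"], dtype=float)
    dirs = prob["dir"]
    b = np.asarray(prob["b"], dtype=float)
    rows_ub = [i for i, d in enumerate(dirs) if d == "<="]
    rows_ge = [i for i, d in enumerate(dirs) if d == ">="]
    A_ub = np.vstack([A[rows_ub], -A[rows_ge]]) if (rows_ub or rows_ge) else None
    b_ub = np.concatenate([b[rows_ub], -b[rows_ge]]) if (rows_ub or rows_ge) else None
    res = linprog(c, A_ub=A_ub, b_ub=b_ub, bounds=(0, None), method="highs")
    if not res.success:
        return None
    return float(res.fun)


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)["problems"]
    values = [solve_one(p) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump({"values": values}, fh)


if __name__ == "__main__":
    main()
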