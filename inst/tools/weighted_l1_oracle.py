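#!/usr/bin/env python
"""High-accuracy reference solver for the weighted l1 problem

    minimise   sum_i w_i |alpha_i|
    subject to ||y - X alpha||_2 <= eps

used as an independent cross-check of the package solver on small instances.
Solves the problem directly (split alpha = p - q, p,q >= 0) with SLSQP,
polished by trust-constr when needed.

Input:  JSON on stdin: a list of instances, each with fields
        d, n, X (flattened column-major), y, w, eps.
Output: JSON on stdout: a list of {objective, residual} per instance.
"""
import json
import sys

import numpy as np
from scipy.optimize import NonlinearConstraint, minimize


def solve(X, y, w, eps):
    d, n = X.shape
    c = np.concatenate([w, w])          # objective: c . z, z = [p; q]
    A = np.hstack([X, -X])              # X alpha = A z

    def resid2(z):
        r = A @ z - y
        return float(r @ r)

    def resid2_grad(z):
        return 2.0 * (A.T @ (A @ z - y))

    cons = NonlinearConstraint(resid2, -np.inf, eps * eps,
                               jac=resid2_grad)
    # feasible start: least-squares solution, split into signs
    alpha0, *_ = np.linalg.lstsq(X, y, rcond=None)
    z0 = np.concatenate([np.clip(alpha0, 0, None), np.clip(-alpha0, 0, None)])
    best = None
    for method, options in (
        ("SLSQP", {"maxiter": 2000, "ftol": 1e-14}),
        ("trust-constr", {"maxiter": 5000, "gtol": 1e-12, "xtol": 1e-14}),
    ):
        res = minimize(lambda z: float(c @ z), z0, jac=lambda z: c,
                       bounds=[(0, None)] * (2 * n), constraints=[cons],
                       method=method, options=options)
        z = np.clip(res.x, 0, None)
        rn = np.sqrt(resid2(z))
        if rn <= eps * (1 + 1e-6):
            obj = float(c @ z)
            if best is None or obj < best[0]:
                best = (obj, float(rn))
        z0 = np.clip(res.x, 0, None)
    if best is None:
        raise RuntimeError("oracle failed to find a feasible point")
    return best


def main():
    instances = json.load(sys.stdin)
    out = []
    for inst in instances:
        d, n = int(inst["d"]), int(inst["n"])
        X = np.asarray(inst["X"], dtype=float).reshape((d, n), order="F")
        y = np.asarray(inst["y"], dtype=float)
        w = np.asarray(inst["w"], dtype=float)
        obj, rn = solve(X, y, w, float(inst["eps"]))
        out.append({"objective": obj, "residual": rn})
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
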