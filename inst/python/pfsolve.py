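"""Mathematical-programming worker for the pathflux R package.

Solves the standard problems pathflux builds in R -- LPs and MILPs via
scipy.optimize.milp (HiGHS) and box/equality-constrained convex QPs with a
diagonal Hessian via trust-constr plus an exact KKT polish -- over a tiny
newline-delimited JSON protocol.  Two entry points:

    pfsolve.py serve <portfile>   persistent worker on a localhost socket
    pfsolve.py once <in> <out>    one-shot file mode (fallback)

Request (one JSON object):
    kind        "milp" | "qp"
    nvar        number of variables
    Aeq/beq     equality constraints, Aeq as {"i","j","x","m"} triplets (0-based)
    Aub/bub     optional inequality constraints  A x <= b
    lb/ub       bounds
    c           linear objective (milp); linear term (qp)
    integrality 0/1 per variable (milp)
    qdiag       diagonal of Q for 0.5 x'Qx + c'x (qp)
    stage2_c    optional lexicographic second objective (milp): re-solve
                minimizing stage2_c subject to c'x <= f1 + tol
    variants    optional list of per-solve overrides of the fields above

Response: {"ok": true, "results": [ {status, x, objective, objective2, kkt} ]}
"""
import json
import socket
import sys

import numpy as np
from scipy.optimize import (Bounds, LinearConstraint, milp, minimize)
from scipy.sparse import csr_matrix

STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
          3: "unbounded", 4: "solver_error"}


def arr(x, dtype=float):
    return np.atleast_1d(np.asarray(x, dtype=dtype))


def triplets(d, nvar):
    if d is None:
        return None
    return csr_matrix((arr(d["x"]), (arr(d["i"], int), arr(d["j"], int))),
                      shape=(int(d["m"]), nvar))


def solve_milp(nvar, Aeq, beq, Aub, bub, lb, ub, c, integrality,
               stage2_c=None):
    cons = []
    if Aeq is not None and Aeq.shape[0]:
        cons.append(LinearConstraint(Aeq, beq, beq))
    if Aub is not None and Aub.shape[0]:
        cons.append(LinearConstraint(Aub, -np.inf, bub))
    bounds = Bounds(lb, ub)
    res = milp(c=c, constraints=cons, integrality=integrality, bounds=bounds)
    if res.status != 0:
        return {"status": STATUS.get(res.status, "solver_error")}
    out = {"status": "optimal", "objective": float(c @ res.x)}
    x = res.x
    if stage2_c is not None:
        f1 = out["objective"]
        tol = 1e-7 + 1e-9 * abs(f1)
        cons2 = cons + [LinearConstraint(csr_matrix(c), -np.inf, f1 + tol)]
        res2 = milp(c=arr(stage2_c), constraints=cons2,
                    integrality=integrality, bounds=bounds)
        if res2.status == 0:
            x = res2.x
            out["objective2"] = float(arr(stage2_c) @ x)
            out["objective"] = float(c @ x)
    out["x"] = [float(v) for v in x]
    return out


def solve_qp(nvar, Aeq, beq, Aub, bub, lb, ub, c, qdiag):
    q = arr(qdiag)

    def fun(x):
        return 0.5 * float(x @ (q * x)) + float(c @ x)

    def jac(x):
        return q * x + c

    cons = []
    if Aeq is not None and Aeq.shape[0]:
        cons.append(LinearConstraint(Aeq, beq, beq))
    if Aub is not None and Aub.shape[0]:
        cons.append(LinearConstraint(Aub, -np.inf, bub))
    x0 = np.clip(np.zeros(nvar), lb, ub)
    res = minimize(fun, x0, jac=jac, hess=lambda x: np.diag(q),
                   method="trust-constr", bounds=Bounds(lb, ub),
                   constraints=cons,
                   options={"gtol": 1e-12, "xtol": 1e-14, "maxiter": 3000})
    x = np.clip(res.x, lb, ub)

    # Active-set KKT polish: with Q diagonal the free block decouples.
    # Start from the bounds trust-constr (nearly) activates, solve the
    # equality-constrained KKT system on the free block, and move any
    # variable the solution pushes out of its box onto that bound; accept
    # the refined point only if it is feasible and no worse.
    if Aeq is not None and Aeq.shape[0]:
        A = Aeq.toarray()
        btol = 1e-5 * (1.0 + np.minimum(np.abs(lb), np.abs(ub)))
        on_lb = x - lb <= btol
        on_ub = ub - x <= btol
        for _ in range(2 * nvar + 2):
            fixed = on_lb | on_ub
            free = ~fixed
            if free.sum() == 0:
                break
            xb = np.where(on_ub, ub, lb)
            rhs_eq = np.asarray(beq, dtype=float) - A[:, fixed] @ xb[fixed]
            nf = int(free.sum())
            K = np.zeros((nf + A.shape[0], nf + A.shape[0]))
            K[:nf, :nf] = np.diag(q[free])
            K[:nf, nf:] = -A[:, free].T
            K[nf:, :nf] = A[:, free]
            rhs = np.concatenate([-c[free], rhs_eq])
            sol, *_ = np.linalg.lstsq(K, rhs, rcond=None)
            xf = sol[:nf]
            idx_free = np.where(free)[0]
            below = xf < lb[idx_free] - 1e-9
            above = xf > ub[idx_free] + 1e-9
            if below.any() or above.any():
                on_lb[idx_free[below]] = True
                on_ub[idx_free[above]] = True
                continue
            cand = np.where(on_ub, ub, np.where(on_lb, lb, x))
            cand[idx_free] = xf
            eqres = np.abs(A @ cand - beq).max() if A.shape[0] else 0.0
            cand = np.clip(cand, lb, ub)
            if eqres <= 1e-7 and fun(cand) <= fun(x) + 1e-9:
                x = cand
            break

    # KKT stationarity residual: project the gradient onto the span of the
    # equality normals and the active-bound unit vectors.
    g = q * x + c
    cols = []
    if Aeq is not None and Aeq.shape[0]:
        cols.append(Aeq.toarray().T)
    btol = 1e-6 * (1.0 + np.maximum(np.abs(lb), np.abs(ub)))
    act = (x - lb <= btol) | (ub - x <= btol)
    if act.any():
        E = np.zeros((nvar, int(act.sum())))
        E[np.where(act)[0], np.arange(int(act.sum()))] = 1.0
        cols.append(E)
    if cols:
        M = np.hstack(cols)
        coef, *_ = np.linalg.lstsq(M, g, rcond=None)
        kkt = float(np.abs(g - M @ coef).max())
    else:
        kkt = float(np.abs(g).max())
    return {"status": "optimal", "x": [float(v) for v in x],
            "objective": fun(x), "kkt": kkt}


def handle(req):
    if req.get("cmd") == "ping":
        return {"ok": True, "pong": True}
    if req.get("cmd") == "quit":
        return {"ok": True, "quit": True}
    nvar = int(req["nvar"])
    base = {k: req.get(k) for k in
            ("Aeq", "beq", "Aub", "bub", "lb", "ub", "c", "integrality",
             "qdiag", "stage2_c")}
    variants = req.get("variants") or [{}]
    results = []
    for ov in variants:
        p = dict(base)
        p.update({k: v for k, v in ov.items() if v is not None})
        Aeq = triplets(p.get("Aeq"), nvar)
        Aub = triplets(p.get("Aub"), nvar)
        lb = arr(p["lb"])
        ub = arr(p["ub"])
        c = arr(p["c"])
        beq = arr(p.get("beq") if p.get("beq") is not None else [])
        bub = arr(p.get("bub") if p.get("bub") is not None else [])
        if req["kind"] == "qp":
            results.append(solve_qp(nvar, Aeq, beq, Aub, bub, lb, ub, c,
                                    p["qdiag"]))
        else:
            integ = arr(p["integrality"], int) if p.get("integrality") is not None else np.zeros(nvar, int)
            results.append(solve_milp(nvar, Aeq, beq, Aub, bub, lb, ub, c,
                                      integ, p.get("stage2_c")))
    return {"ok": True, "results": results}


def serve(portfile):
    srv = socket.create_server(("127.0.0.1", 0))
    port = srv.getsockname()[1]
    with open(portfile, "w") as fh:
        fh.write(str(port))
    srv.settimeout(60)
    try:
        conn, _ = srv.accept()
    except socket.timeout:
        return
    conn.settimeout(None)
    fh = conn.makefile("rwb")
    while True:
        line = fh.readline()
        if not line:
            break
        try:
            req = json.loads(line.decode("utf-8"))
            resp = handle(req)
        except Exception as exc:  # report, keep serving
            resp = {"ok": False, "error": str(exc)}
        fh.write((json.dumps(resp) + "\n").encode("utf-8"))
        fh.flush()
        if resp.get("quit"):
            break
    conn.close()
    srv.close()


def once(infile, outfile):
    with open(infile) as fh:
        req = json.load(fh)
    try:
        resp = handle(req)
    except Exception as exc:
        resp = {"ok": False, "error": str(exc)}
    with open(outfile, "w") as fh:
        json.dump(resp, fh)


if __name__ == "__main__":
    if sys.argv[1] == "serve":
        serve(sys.argv[2])
    elif sys.argv[1] == "once":
        once(sys.argv[2], sys.argv[3])
    else:
        raise SystemExit("usage: pfsolve.py serve <portfile> | once <in> <out>")
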