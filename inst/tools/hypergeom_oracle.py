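"""Exact-rational hypergeometric upper-tail oracle.

Reads whitespace-separated instances "k K n N" (one per line) on stdin and
prints, per line, P(X >= k) for X ~ Hypergeometric(N, K, n): the tail sum
is accumulated in exact integer arithmetic and divided exactly (via
Fraction) so the printed double is the correctly rounded value of the
exact rational probability.
"""
import sys
from fractions import Fraction
from math import comb


def upper_tail(k, K, n, N):
    num = sum(comb(K, i) * comb(N - K, n - i)
              for i in range(k, min(K, n) + 1))
    return float(Fraction(num, comb(N, n)))


def main():
    out = []
    for line in sys.stdin:
        parts = line.split()
        if parts:
            k, K, n, N = map(int, parts)
            out.append(repr(upper_tail(k, K, n, N)))
    sys.stdout.write("\n".join(out) + "\n")


if __name__ == "__main__":
    main()
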