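# The 22 points of the long 3-path of dimension 9, in path order.
long_path_9_3 <- c(
  "000000000", "000000001", "000000011", "000000111", "000001111",
  "000011111", "000111111", "000111011", "000111001", "000111000",
  "001111000", "011111000", "111111000", "111111001", "111111011",
  "111111111", "111011111", "111001111", "111000111", "111000011",
  "111000001", "111000000")

# Kimura fixation probabilities computed independently with 50-digit
# arithmetic (sympy), covering small, moderate and extreme exponents
# (|2*N*beta*delta_f| up to 700).
pfix_reference <- data.frame(
  beta = c(0.1, 0.1, 1, 1, 1, 1, 5, 5, 1, 1, 0.5, 2, 0.25, 0.25),
  N = c(2, 2, 2, 2, 5, 5, 20, 20, 10, 10, 7, 3, 2, 2),
  delta_f = c(0.01, -0.01, 1, -1, 3, -3, 0.5, -0.5, 30, -30, -100, 58,
              -1e-6, 1e-6),
  pfix = c(
    0.50049999983333339999997301588395061285233464839614,
    0.49950000016666660000002698411604938714766535160386,
    0.88079707797788244405972914130239679520638429862897,
    0.11920292202211755594027085869760320479361570137103,
    0.99752124782342698585436021869309920178866764821252,
    3.7657769213106099642461975593260339042019093194562e-11,
    0.99326205300091453290336395157685157575115045192275,
    5.4838815172683243720940451086408408900138156440556e-42,
    0.99999999999999999999999999124348923730347966151127,
    3.0267724494729399148714860259110286330893420776088e-235,
    2.6503965530043108163386794472695827015290924513465e-261,
    1.0,
    0.49999987500000000000260416666666660156250000000165,
    0.50000012499999999999739583333333339843749999999835))
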