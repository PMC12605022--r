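Fp1 0.951056516295154 0.309016994374947 6.12323399573677e-17
Fp2 0.951056516295154 -0.309016994374947 6.12323399573677e-17
F7 0.587785252292473 0.809016994374947 6.12323399573677e-17
F3 0.686179155968469 0.555656924414492 0.469471562785891
Fz 0.707106781186547 0 0.707106781186548
F4 0.686179155968469 -0.555656924414492 0.469471562785891
F8 0.587785252292473 -0.809016994374947 6.12323399573677e-17
T3 6.12323399573677e-17 1 6.12323399573677e-17
C3 4.32978028117747e-17 0.707106781186547 0.707106781186548
Cz 0 0 1
C4 4.32978028117747e-17 -0.707106781186547 0.707106781186548
T4 6.12323399573677e-17 -1 6.12323399573677e-17
T5 -0.587785252292473 0.809016994374947 6.12323399573677e-17
P3 -0.686179155968469 0.555656924414493 0.469471562785891
Pz -0.707106781186547 8.65956056235493e-17 0.707106781186548
P4 -0.686179155968469 -0.555656924414493 0.469471562785891
T6 -0.587785252292473 -0.809016994374947 6.12323399573677e-17
O1 -0.951056516295154 0.309016994374948 6.12323399573677e-17
O2 -0.951056516295154 -0.309016994374948 6.12323399573677e-17
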