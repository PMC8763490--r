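#ifndef PULMOSTAGE_EDT_H
#define PULMOSTAGE_EDT_H

// Euclidean distance (physical units) from every pixel to the nearest
// nonzero pixel of `mask` (H x W, column-major). Out must hold H*W doubles.
void edt_raw(const unsigned char* mask, int H, int W, double sy, double sx,
             double* out);

#endif
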