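471.93,502.63,528.95,546.61,552.69,546.21,528.29,502.02,471.88,442.96,419.96
477.7,508.63,535.3,553.45,560.13,554.28,536.92,511.04,481.03,451.88,428.28
483.64,512.45,537.49,554.87,561.83,557.3,542.09,518.79,491.33,464.18,441.6
489.31,513.89,535.5,550.93,557.83,555.18,543.49,524.72,501.96,478.82,458.77
494.21,512.87,529.59,542.09,548.6,548.22,541.06,528.31,511.95,494.43,478.15
497.8,509.41,520.27,529.16,535,537.03,535,529.16,520.27,509.41,497.8
499.59,503.71,508.29,513.23,518.18,522.56,525.72,527.01,525.93,522.15,515.64
499.22,496.13,494.63,495.66,499.58,506,513.92,521.87,528.17,531.21,529.76
496.61,487.28,480.46,478.01,480.85,488.8,500.59,514.08,526.63,535.55,538.64
491.99,477.98,467.14,461.95,463.78,472.6,486.99,504.36,521.41,534.73,541.41
485.9,469.23,456.05,449.14,450.12,459.07,474.52,493.73,513.11,528.91,537.86
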