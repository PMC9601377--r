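20
POL  0.000  0.037  0.064  0.124  0.044  0.107  0.079  0.163  0.049  0.036  0.033  0.045  0.106  0.155  0.053  0.035  0.098  0.063  0.050  0.116
ESP  0.037  0.000  0.056  0.130  0.047  0.090  0.090  0.144  0.043  0.039  0.038  0.039  0.108  0.135  0.043  0.034  0.082  0.051  0.043  0.122
MEX  0.064  0.056  0.000  0.129  0.062  0.098  0.127  0.142  0.056  0.064  0.063  0.050  0.116  0.128  0.052  0.057  0.085  0.059  0.045  0.120
KOR  0.124  0.130  0.129  0.000  0.136  0.166  0.193  0.224  0.135  0.140  0.127  0.122  0.059  0.227  0.125  0.132  0.172  0.135  0.125  0.041
FIN  0.044  0.047  0.062  0.136  0.000  0.103  0.090  0.147  0.056  0.044  0.041  0.054  0.121  0.137  0.058  0.042  0.088  0.056  0.046  0.125
SOM  0.107  0.090  0.098  0.166  0.103  0.000  0.149  0.071  0.084  0.108  0.106  0.088  0.138  0.067  0.070  0.098  0.050  0.059  0.073  0.146
PAK  0.079  0.090  0.127  0.193  0.090  0.149  0.000  0.198  0.105  0.081  0.078  0.103  0.176  0.192  0.111  0.077  0.137  0.107  0.099  0.178
ZAZ  0.163  0.144  0.142  0.224  0.147  0.071  0.198  0.000  0.132  0.166  0.161  0.147  0.213  0.038  0.107  0.148  0.052  0.076  0.109  0.214
IRQ  0.049  0.043  0.056  0.135  0.056  0.084  0.105  0.132  0.000  0.051  0.048  0.034  0.112  0.120  0.037  0.045  0.073  0.050  0.045  0.122
LTU  0.036  0.039  0.064  0.140  0.044  0.108  0.081  0.166  0.051  0.000  0.034  0.048  0.116  0.157  0.057  0.037  0.102  0.065  0.051  0.125
SLO  0.033  0.038  0.063  0.127  0.041  0.106  0.078  0.161  0.048  0.034  0.000  0.044  0.108  0.151  0.052  0.033  0.096  0.061  0.048  0.117
TUR  0.045  0.039  0.050  0.122  0.054  0.088  0.103  0.147  0.034  0.048  0.044  0.000  0.098  0.137  0.038  0.040  0.084  0.054  0.045  0.109
VIE  0.106  0.108  0.116  0.059  0.121  0.138  0.176  0.213  0.112  0.116  0.108  0.098  0.000  0.214  0.107  0.109  0.158  0.119  0.109  0.047
NGA  0.155  0.135  0.128  0.227  0.137  0.067  0.192  0.038  0.120  0.157  0.151  0.137  0.214  0.000  0.100  0.141  0.043  0.071  0.101  0.217
BHR  0.053  0.043  0.052  0.125  0.058  0.070  0.111  0.107  0.037  0.057  0.052  0.038  0.107  0.100  0.000  0.046  0.060  0.039  0.039  0.116
ZAA  0.035  0.034  0.057  0.132  0.042  0.098  0.077  0.148  0.045  0.037  0.033  0.040  0.109  0.141  0.046  0.000  0.087  0.054  0.042  0.119
ANG  0.098  0.082  0.085  0.172  0.088  0.050  0.137  0.052  0.073  0.102  0.096  0.084  0.158  0.043  0.060  0.087  0.000  0.042  0.060  0.162
MOZ  0.063  0.051  0.059  0.135  0.056  0.059  0.107  0.076  0.050  0.065  0.061  0.054  0.119  0.071  0.039  0.054  0.042  0.000  0.039  0.125
BRA  0.050  0.043  0.045  0.125  0.046  0.073  0.099  0.109  0.045  0.051  0.048  0.045  0.109  0.101  0.039  0.042  0.060  0.039  0.000  0.115
CHN  0.116  0.122  0.120  0.041  0.125  0.146  0.178  0.214  0.122  0.125  0.117  0.109  0.047  0.217  0.116  0.119  0.162  0.125  0.115  0.000
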