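#system
You will be given characteristics of a sample.
Classify the sample outcome into one of the following categories: 0, or 1.
Return only the name of the category, and nothing else.
MAKE SURE your output is one of the two categories stated.
#user
C0 is -0.26, C1 is 2.14, C2 is 0.15, C3 is 1.96, C4 is 1.5, C5 is 0.15, C6 is 0.43, C7 is -1.8, C8 is -1.22, C9 is 0.5, C10 is -0.93, C11 is -1.29, C12 is 0.95, C13 is 1.74, C14 is -1.13, C15 is -1.08, C16 is 0.41, C17 is -0.86, C18 is 0.07, C19 is 1.0. Outcome is ->
#assistant
1
#user
C0 is 1.92, C1 is 0.76, C2 is 0.55, C3 is 1.41, C4 is 1.5, C5 is -0.45, C6 is 0.84, C7 is 0.93, C8 is -1.01, C9 is -0.68, C10 is -0.93, C11 is 1.67, C12 is -0.65, C13 is -0.56, C14 is 1.21, C15 is 0.5, C16 is -0.79, C17 is 0.72, C18 is 0.73, C19 is -1.0. Outcome is ->
#assistant
0
#user
C0 is -1.16, C1 is -0.22, C2 is 0.17, C3 is -0.49, C4 is -0.78, C5 is -1.27, C6 is -1.5, C7 is -0.86, C8 is -0.37, C9 is -0.76, C10 is 0.84, C11 is 0.43, C12 is 0.4, C13 is 0.08, C14 is 0.9, C15 is -0.3, C16 is -0.63, C17 is -0.86, C18 is -1.92, C19 is -1.0. Outcome is ->
#assistant
0
#user
C0 is -0.11, C1 is -0.62, C2 is -0.28, C3 is -0.57, C4 is -0.71, C5 is -0.77, C6 is 0.02, C7 is 0.66, C8 is 0.32, C9 is -0.53, C10 is 0.25, C11 is 0.24, C12 is -1.06, C13 is -0.93, C14 is -0.37, C15 is 0.42, C16 is 2.32, C17 is 1.01, C18 is 0.73, C19 is 1.0. Outcome is ->
#assistant
0
#user
C0 is 0.66, C1 is -0.98, C2 is -2.44, C3 is -0.87, C4 is -0.53, C5 is 2.25, C6 is -1.75, C7 is -0.65, C8 is -0.95, C9 is 2.02, C10 is 0.84, C11 is -0.9, C12 is -1.27, C13 is -0.74, C14 is -0.21, C15 is 0.06, C16 is -0.79, C17 is -1.45, C18 is 0.07, C19 is 1.0. Outcome is ->
#assistant
0
#user
C0 is -0.78, C1 is -0.1, C2 is 0.12, C3 is -0.36, C4 is -0.78, C5 is 0.53, C6 is 0.31, C7 is 0.11, C8 is 0.8, C9 is 0.23, C10 is 1.87, C11 is 1.1, C12 is 0.95, C13 is -0.84, C14 is 1.41, C15 is -0.66, C16 is 1.33, C17 is 0.72, C18 is 0.73, C19 is -1.0. Outcome is ->
#assistant
0
#user
C0 is 1.18, C1 is 1.27, C2 is 0.57, C3 is 0.62, C4 is -0.17, C5 is 0.7, C6 is 1.79, C7 is 1.16, C8 is -0.17, C9 is 1.35, C10 is 0.84, C11 is 1.1, C12 is -0.02, C13 is 0.17, C14 is 0.5, C15 is -0.91, C16 is -0.43, C17 is 1.11, C18 is 0.73, C19 is -1.0. Outcome is ->
#assistant
0
#user
C0 is -0.67, C1 is -0.94, C2 is -0.6, C3 is 0.38, C4 is -0.78, C5 is -0.69, C6 is -0.37, C7 is -1.2, C8 is 1.12, C9 is -1.05, C10 is -0.93, C11 is -0.43, C12 is -0.16, C13 is 1.28, C14 is -1.94, C15 is -0.27, C16 is -0.14, C17 is -1.54, C18 is -1.92, C19 is 1.0. Outcome is ->
#assistant
0
#user
C0 is -1.31, C1 is -0.49, C2 is 0.04, C3 is -1.15, C4 is -0.75, C5 is -0.98, C6 is 0.52, C7 is 1.11, C8 is 2.03, C9 is -1.17, C10 is -0.93, C11 is -0.71, C12 is -1.06, C13 is -1.3, C14 is -0.52, C15 is 2.61, C16 is -0.68, C17 is 0.32, C18 is 0.07, C19 is -1.0. Outcome is ->
#assistant
0
#user
C0 is 0.53, C1 is -0.82, C2 is 1.71, C3 is -0.93, C4 is 1.5, C5 is 0.54, C6 is -0.29, C7 is 0.54, C8 is -0.55, C9 is 0.09, C10 is -0.93, C11 is -1.19, C12 is 1.93, C13 is 1.09, C14 is 0.14, C15 is -0.36, C16 is -0.59, C17 is 0.82, C18 is 0.73, C19 is 1.0. Outcome is ->
#assistant
0
#user
C0 is -2.65, C1 is 0.2, C2 is -0.6, C3 is -0.23, C4 is -0.74, C5 is 0.15, C6 is 1.39, C7 is 0.95, C8 is 0.88, C9 is -1.67, C10 is -0.93, C11 is -0.81, C12 is 2.06, C13 is -0.47, C14 is 0.95, C15 is -0.75, C16 is -0.61, C17 is -0.76, C18 is 0.73, C19 is -1.0. Outcome is ->
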