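#' Reference classifiers on the same data draws
#'
#' Thin adapter around established implementations — CART (`rpart`),
#' k-nearest neighbours (`class::knn`, k = 5) and random forest
#' (`randomForest`) — used only for side-by-side comparison in the
#' simulation harness. Returns the test misclassification rate.
#'
#' @param train,test [labeled_dataset()]s.
#' @param method `"cart"`, `"knn"` or `"rf"`.
#' @param knn_k neighbourhood size for `"knn"`.
#' @return test error rate in \[0, 1\].
#' @export
fit_baseline <- function(train, test, method = c("cart", "knn", "rf"),
                         knn_k = 5) {
  method <- match.arg(method)
  ytr <- factor(train$labels, levels = c(-1, 1))
  pred <- switch(method,
    cart = {
      if (!requireNamespace("rpart", quietly = TRUE)) {
        stop("baseline 'cart' requires the 'rpart' package")
      }
      df <- data.frame(y = ytr, train$features)
      nd <- data.frame(test$features)
      colnames(nd) <- colnames(df)[-1]
      predict(rpart::rpart(y ~ ., df, method = "class"), nd, type = "class")
    },
    knn = {
      if (!requireNamespace("class", quietly = TRUE)) {
        stop("baseline 'knn' requires the 'class' package")
      }
      class::knn(train$features, test$features, ytr, k = knn_k)
    },
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("baseline 'rf' requires the 'randomForest' package")
      }
      predict(randomForest::randomForest(train$features, ytr),
              test$features)
    })
  mean(as.numeric(as.character(pred)) != test$labels)
}
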